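model,epoch_s,predicted,chew,rest,swim,vertical_swim
SVM,2,chew,13,0,1,0
SVM,2,rest,2,20,2,0
SVM,2,swim,4,0,32,0
SVM,2,vertical_swim,0,0,0,8
SVM,1,chew,8,2,4,0
SVM,1,rest,3,19,2,0
SVM,1,swim,8,0,28,0
SVM,1,vertical_swim,0,0,0,8
RF,2,chew,10,0,4,0
RF,2,rest,1,21,2,0
RF,2,swim,2,0,34,0
RF,2,vertical_swim,0,0,0,8
RF,1,chew,7,2,5,0
RF,1,rest,1,21,2,0
RF,1,swim,2,0,34,0
RF,1,vertical_swim,0,0,0,8
XGB,2,chew,11,0,3,0
XGB,2,rest,1,21,2,0
XGB,2,swim,4,0,32,0
XGB,2,vertical_swim,0,0,0,8
XGB,1,chew,5,1,8,0
XGB,1,rest,0,21,3,0
XGB,1,swim,4,1,31,0
XGB,1,vertical_swim,0,0,0,8
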