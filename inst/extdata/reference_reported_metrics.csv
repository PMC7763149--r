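model,epoch_s,class,sensitivity,specificity,precision,f_measure
SVM,2,chew,68.4,98.4,92.9,78.8
SVM,2,rest,100,93.6,83.3,90.9
SVM,2,swim,91.4,91.5,88.9,90.1
SVM,2,vertical_swim,100,100,100,100
SVM,1,chew,42.1,90.5,57.1,48.5
SVM,1,rest,90.5,91.8,79.2,84.4
SVM,1,swim,82.4,83.3,77.8,80
SVM,1,vertical_swim,100,100,100,100
RF,2,chew,77,94.2,71.4,74.1
RF,2,rest,100,95.1,87.5,93.3
RF,2,swim,85,95.2,94.4,89.5
RF,2,vertical_swim,100,100,100,100
RF,1,chew,70,90.3,50,58.3
RF,1,rest,91.3,95,87.5,89.4
RF,1,swim,83,95.1,94.4,88.3
RF,1,vertical_swim,100,100,100,100
XGB,2,chew,68.8,95.5,78.6,73.3
XGB,2,rest,100,95.1,87.5,93.3
XGB,2,swim,86.5,91.1,88.9,87.7
XGB,2,vertical_swim,100,100,100,100
XGB,1,chew,55.6,87.7,35.7,43.5
XGB,1,rest,91.3,95,87.5,89.4
XGB,1,swim,73.8,87.5,86.1,79.5
XGB,1,vertical_swim,100,100,100,100
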