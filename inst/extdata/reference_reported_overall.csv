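model,epoch_s,accuracy,macro_f
SVM,2,89,90
RF,2,89,89.2
XGB,2,87.8,88.6
SVM,1,76.8,78.2
RF,1,85.4,84
XGB,1,79.3,78.1
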