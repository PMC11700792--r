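technique,dataset,fpr,specificity,sensitivity,accuracy,time_s
SVM,malignant,5.95,94.05,96.69,95.90,59.89
CS-SVM,malignant,3.57,96.43,97.71,97.33,39.87
SVM,benign,11.11,88.89,91.67,90.83,59.92
CS-SVM,benign,5.56,94.44,94.05,94.17,39.86
SVM,normal,9.60,90.40,94.85,93.51,61.74
CS-SVM,normal,6.40,93.60,96.22,95.43,40.40
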