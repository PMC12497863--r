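ligand,receptor,tpm2,tpm10,role
TNFSF10,TNFRSF10A,YES,YES,Activation
TNF,TNFRSF1A,YES,YES,Activation
SEMA7A,PLXNC1,YES,NO,Memory generation
SEMA4D,CD72,YES,YES,Effector function
SELPLG,SELP,YES,NO,Migration/Infiltration
SELPLG,SELL,YES,YES,Migration/Infiltration
CD274,PDCD1,YES,NO,Regulatory function
GZMA,F2R,YES,NO,Regulatory function
DLL1,NOTCH1,YES,YES,Effector function
TNFSF14,TNFRSF14,YES,YES,Activation
ITGAL/ITGB2,CD226,YES,YES,Activation/Effector function
FASLG,FAS,YES,YES,Regulatory function
EFNA1,EPHA4,YES,NO,Regulatory function
CD99,PILRA,YES,NO,Activation
CD6,ALCAM,YES,YES,Effector function
BAG6,NCR3,YES,NO,Effector function
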