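cell_line,pik3ca_mutation,tp53_mutation,cisplatin_ic50
BT20,H1047R/P539R,K132Q,0.43
CAL-51,E542K,WT,2.10
CAL85-1,WT,K132E,0.47
HCC1143,WT,R248Q,1.07
HDQ-P1,WT,R213*,6.33
MDA-MB-157,WT,FS Del,8.90
MDA-MB-231,WT,R280K,2.13
MDA-MB-468,WT,R273H,0.23
MFM-223,H1047R,K132R,>10
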