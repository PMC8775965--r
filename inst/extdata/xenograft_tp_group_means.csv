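group,antibody,mean_tp_ratio
LS174T,non-binding,0.26
LS174T,target-binding,0.41
LS174T/Sorafenib,non-binding,0.20
LS174T/Sorafenib,target-binding,0.27
NCI-N87,non-binding,0.19
NCI-N87,target-binding,0.48
Panc-1,non-binding,0.08
Panc-1,target-binding,0.12
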