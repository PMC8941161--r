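# Minimum accepted hmmsearch bit scores per HMM model.  These placeholder
# defaults MUST be overridden with the score cutoffs calibrated for the HMM
# collection actually used; they exist so the pipeline runs end to end.
coxL_form1: 500
coxL_form2: 500
coxG: 100
NiCODH: 200
Hyd_3b: 100
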