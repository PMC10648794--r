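cohort,n_wsi,n_white_discarded,n_labeled
DC,20,53000,2548
RC,37,104500,3419
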