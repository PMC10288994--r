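# Artifact-prone genes (repeat regions, paralog families, highly expressed
# housekeeping genes): fusions touching them are discarded.
HLA-A
HLA-B
HLA-DRB1
GAPDH
ACTB
RPL10
MT-CO1
MT-ND4
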