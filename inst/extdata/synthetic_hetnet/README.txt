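Synthetic stochastic-block-model network in the deposited edge-list
layout (one TSV per relation + community labels). Generated by
synth_hetnet(synth_config(n_G = 40, n_D = 20, n_O = 30, n_S = 10,
seed = 424242)). Not real biomedical data.
Generated counts (as loaded from the edge lists): 40 genes, 20
diseases, 29 GO terms with >=1 annotation, 9 symptoms with >=1
association; 110 G-G / 147 G-D / 182 G-O / 23 D-S edges.
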