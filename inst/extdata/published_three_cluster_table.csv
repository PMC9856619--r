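outcome,cluster_A,cluster_C,cluster_B
presence,4,16,50
absence,41,77,106
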