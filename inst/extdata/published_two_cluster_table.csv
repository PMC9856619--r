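outcome,cluster_O,cluster_B
presence,20,50
absence,118,106
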