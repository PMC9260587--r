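# ethoclust config_hash=04cba3d0 seed=424242
Cluster 0 - Low time until approach, Low trajectory length, High total contact, High straightness, High contact ratio
Cluster 1 - High time until approach, High trajectory length, Low total contact, Low straightness, Low contact ratio
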