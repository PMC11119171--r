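lesion_diameter_cm,distance_range_cm,n_punctures,n_hits
5,4-10,24,24
2,3.6-8,24,23
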