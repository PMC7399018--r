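wavelength_nm	HbO	HbR
760	586.0	1548.52
850	1058.0	691.32
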