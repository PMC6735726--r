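toy	5857	7357
toy	13214	14714
toy	20571	22071
toy	27928	29428
toy	35285	36785
toy	42642	44142
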