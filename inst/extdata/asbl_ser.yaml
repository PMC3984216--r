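# asbl_ser scenario preset: package defaults for every parameter block
scenario: asbl_ser
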