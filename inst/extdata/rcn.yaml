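# rcn scenario preset: package defaults for every parameter block
scenario: rcn
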