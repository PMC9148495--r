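3b544fc70fc66f6c339b25cfabd93e2b
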