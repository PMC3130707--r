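stage	n
examined	1223
predicted	532
reliable	273
networked	232
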