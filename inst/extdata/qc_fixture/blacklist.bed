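chrS	2700	2800
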