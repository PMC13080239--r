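Col1a1
Col1a2
Col3a1
Col4a1
Col5a1
Col5a2
Col6a1
Col6a2
Col6a3
Col15a1
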