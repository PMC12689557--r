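butanoate metabolism
citrate cycle (TCA cycle)
propanoate metabolism
glutathione metabolism
vitamin B6 metabolism
steroid hormone biosynthesis
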