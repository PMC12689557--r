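purine metabolism
tryptophan metabolism
vitamin B6 metabolism
nicotinate and nicotinamide metabolism
histidine metabolism
glutathione metabolism
arginine and proline metabolism
tyrosine metabolism
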