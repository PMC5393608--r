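specimen_id	species	genus
J101	Litsea elongata	Litsea
J102	Litsea elongata	Litsea
J201	Litsea salicifolia	Litsea
J202	Litsea salicifolia	Litsea
J301	Machilus grijsii	Machilus
J302	Machilus grijsii	Machilus
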