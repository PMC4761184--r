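OOO	triperoxide_chain
NF	n_fluoride
NCl	n_chloride
NBr	n_bromide
NI	n_iodide
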