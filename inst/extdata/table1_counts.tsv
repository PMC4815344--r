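class	core	support	rim	interior	surface
rare	1516	828	1748	7015	8533
intermediate	20	8	29	109	176
common	14	5	36	83	185
nonvariant	27154	17725	26799	146816	128860
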