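species	sample_no	lid	pitcher
Sarracenia alata 'Black Tube'		x	x*
Sarracenia alata		x	x
Sarracenia flava	20	x*	-
Sarracenia flava var. atropurpurea		x*	x*
Sarracenia flava var. maxima	44	x*	x*
Sarracenia flava var. ornata		x	x*
Sarracenia leucophylla		x
Sarracenia minor var. okefenokeensis	5	x	-
Sarracenia oreophila		-	x
Sarracenia psittacina	13		x
Sarracenia psittacina	43	x	x
Sarracenia purpurea subsp. burkii		x	x
Sarracenia purpurea subsp. venosa	36	x	x
Sarracenia purpurea subsp. venosa var. burkii f. luteola	48	x	x
Sarracenia purpurea subsp. venosa var. montana	41	x	x
Sarracenia rubra subsp. alabamensis		x	x
Sarracenia rubra subsp. gulfensis		x	x
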