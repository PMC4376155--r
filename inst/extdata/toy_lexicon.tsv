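good	2.0
great	2.0
relief	2.0
excellent	3.0
happy	1.0
thanks	1.0
covered	1.0
affordable	1.0
works	1.0
glad	1.0
bad	-1.0
broken	-1.0
expensive	-1.0
penalty	-1.0
joke	-2.0
fail	-2.0
sucks	-2.0
awful	-3.0
terrible	-3.0
disaster	-3.0
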