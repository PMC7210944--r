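group	mass_kg	note
small ungulate	30	synthetic: standard wildlife reference value (roe-deer-sized)
roe deer	25	synthetic: standard wildlife reference value
medium ungulate	120	synthetic: standard wildlife reference value (reindeer/red deer sized)
red deer	200	synthetic: standard wildlife reference value
large ungulate	600	synthetic: standard wildlife reference value (horse/large bovid sized)
large bovid	700	synthetic: standard wildlife reference value (bison/aurochs)
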