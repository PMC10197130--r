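"restype","ca","cb"
"A",52.62,19.22
"R",56.12,31.02
"N",53.22,39.02
"D",54.32,41.22
"C",58.32,28.12
"Q",55.82,29.52
"E",56.72,30.02
"G",45.22,NA
"H",55.12,29.12
"I",61.22,38.92
"L",55.22,42.52
"K",56.42,33.02
"M",55.52,33.02
"F",57.82,39.72
"P",63.42,32.22
"S",58.42,63.92
"T",61.92,69.92
"W",57.62,29.72
"Y",58.02,38.92
"V",62.32,33.02
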