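Name: HMDB00251|[M-H]-|negative
PrecursorMZ: 124.0072
Source: in_silico
Num Peaks: 3
79.9573 100.0
106.9808 35.0
124.0074 20.0

Name: HMDB00157|[M+H]+|positive
PrecursorMZ: 137.0478
Source: in_silico
Num Peaks: 3
94.0400 30.0
110.0349 100.0
119.0352 45.0

Name: HMDB00929|[M-H]-|negative
PrecursorMZ: 203.0824
Source: in_silico
Num Peaks: 3
74.0242 40.0
116.0506 100.0
142.0662 60.0

Name: HMDB00929|[M+H]+|positive
PrecursorMZ: 205.0968
Source: in_silico
Num Peaks: 5
115.0542 20.0
118.0651 45.0
144.0808 35.0
146.0600 100.0
188.0706 60.0

Name: HMDB00881|[M+H]+|positive
PrecursorMZ: 206.0458
Source: in_silico
Num Peaks: 3
132.0444 40.0
160.0393 100.0
188.0342 55.0
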