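label,phase_class,age_start,age_end
GI 1,GI,12.0,10.0
GS 1,GS,13.3,12.0
GI 2,GI,15.0,13.3
HS 1,HS,17.5,15.0
GI 3,GI,19.4,17.5
GS 2,GS,20.6,19.4
GI 4,GI,22.4,20.6
HS 2,HS,25.0,22.4
GI 5,GI,26.8,25.0
GS 3,GS,28.0,26.8
GI 6,GI,29.8,28.0
HS 3,HS,32.3,29.8
GI 7,GI,34.1,32.3
GS 4,GS,35.3,34.1
GI 8,GI,38.2,35.3
HS 4,HS,40.2,38.2
GI 9,GI,41.9,40.2
GS 5,GS,43.2,41.9
GI 10,GI,45.0,43.2
HS 5,HS,48.6,45.0
GI 11,GI,50.4,48.6
GS 6,GS,51.6,50.4
GI 12,GI,54.6,51.6
GS 7,GS,55.8,54.6
GI 13,GI,57.6,55.8
HS 6,HS,61.1,57.6
GI 14,GI,64.1,61.1
GS 8,GS,65.3,64.1
GI 15,GI,67.0,65.3
GS 9,GS,68.2,67.0
GI 16,GI,70.0,68.2
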