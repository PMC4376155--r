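code,name,rep_lat,rep_lon
AK,Alaska,64,-152
AL,Alabama,32.8,-86.8
AR,Arkansas,34.8,-92.3
AZ,Arizona,34.3,-111.7
CA,California,36.5,-119.3
CO,Colorado,39,-105.5
CT,Connecticut,41.6,-72.7
DC,District of Columbia,38.9,-77.02
DE,Delaware,38.9,-75.4
FL,Florida,28.6,-81.5
GA,Georgia,32.7,-83.4
HI,Hawaii,20.5,-157.5
IA,Iowa,42,-93.5
ID,Idaho,44.3,-114.2
IL,Illinois,40,-89.2
IN,Indiana,40,-86.3
KS,Kansas,38.5,-98
KY,Kentucky,37.5,-85.3
LA,Louisiana,31.1,-92.5
MA,Massachusetts,42.3,-71.8
MD,Maryland,39.45,-77
ME,Maine,45.3,-69
MI,Michigan,43,-84.6
MN,Minnesota,46.3,-94.3
MO,Missouri,38.4,-92.5
MS,Mississippi,33.5,-89.4
MT,Montana,47,-109.5
NC,North Carolina,35.5,-79.2
ND,North Dakota,47.4,-100.5
NE,Nebraska,41.5,-99.8
NH,New Hampshire,43.7,-71.6
NJ,New Jersey,40.1,-74.6
NM,New Mexico,34.4,-106.1
NV,Nevada,39.3,-116.9
NY,New York,43,-75.5
OH,Ohio,40.3,-82.7
OK,Oklahoma,35.5,-97.5
OR,Oregon,43.9,-120.6
PA,Pennsylvania,40.9,-77.8
RI,Rhode Island,41.7,-71.5
SC,South Carolina,33.5,-80.6
SD,South Dakota,44.4,-100.3
TN,Tennessee,35.8,-86.4
TX,Texas,31.2,-99
UT,Utah,39.5,-111.5
VA,Virginia,37.55,-78.3
VT,Vermont,44,-72.7
WA,Washington,47.4,-120.3
WI,Wisconsin,44.6,-89.7
WV,West Virginia,38.6,-80.6
WY,Wyoming,43,-107.5
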