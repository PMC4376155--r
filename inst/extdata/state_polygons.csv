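state,lon,lat
AK,-168,54.5
AK,-130,54.5
AK,-130,71.3
AK,-168,71.3
AL,-88.47,30.25
AL,-84.89,30.25
AL,-84.89,35
AL,-88.47,35
AR,-94.62,33
AR,-89.64,33
AR,-89.64,36.5
AR,-94.62,36.5
AZ,-114.81,31.35
AZ,-109.05,31.35
AZ,-109.05,37
AZ,-114.81,37
CA,-124.3,42
CA,-120,42
CA,-120,39.1
CA,-114.7,35
CA,-114.7,34
CA,-116,32.65
CA,-117.3,32.55
CA,-118.5,33.9
CA,-120.8,34.5
CA,-122.6,37.1
CA,-124.3,40
CO,-109.05,37
CO,-102.04,37
CO,-102.04,41
CO,-109.05,41
CT,-73.73,40.99
CT,-71.79,40.99
CT,-71.79,42.05
CT,-73.73,42.05
DC,-77.12,38.8
DC,-76.9,38.8
DC,-76.9,38.995
DC,-77.12,38.995
DE,-75.79,38.45
DE,-75.05,38.45
DE,-75.05,39.84
DE,-75.79,39.84
FL,-87.63,24.52
FL,-80.03,24.52
FL,-80.03,31
FL,-87.63,31
GA,-85.61,30.36
GA,-80.84,30.36
GA,-80.84,35
GA,-85.61,35
HI,-160.25,18.9
HI,-154.8,18.9
HI,-154.8,22.24
HI,-160.25,22.24
IA,-96.64,40.38
IA,-90.14,40.38
IA,-90.14,43.5
IA,-96.64,43.5
ID,-117.2,42
ID,-111.05,42
ID,-111.05,44.5
ID,-113,44.5
ID,-113,45.7
ID,-114.5,45.7
ID,-114.5,49
ID,-117,49
IL,-91.51,37
IL,-87.5,37
IL,-87.5,42.5
IL,-91.51,42.5
IN,-88.1,37.77
IN,-84.78,37.77
IN,-84.78,41.76
IN,-88.1,41.76
KS,-102.05,37
KS,-94.59,37
KS,-94.59,40
KS,-102.05,40
KY,-89.57,36.5
KY,-81.96,36.5
KY,-81.96,39.15
KY,-89.57,39.15
LA,-94.04,33
LA,-91.1,33
LA,-91.6,31
LA,-89.7,31
LA,-89.2,30.15
LA,-89,29.3
LA,-90.2,28.9
LA,-93.8,29.6
LA,-94.04,29.7
MA,-73.5,42.05
MA,-71.8,42
MA,-71.38,42
MA,-71.38,41.78
MA,-71.12,41.66
MA,-70.4,41.55
MA,-69.93,41.65
MA,-70,42.1
MA,-70.6,42.68
MA,-71,42.87
MA,-72,42.73
MA,-73.26,42.75
MD,-79.49,37.92
MD,-75.05,37.92
MD,-75.05,39.72
MD,-79.49,39.72
ME,-71.08,43.06
ME,-66.95,43.06
ME,-66.95,47.46
ME,-71.08,47.46
MI,-86.8,41.72
MI,-82.45,41.72
MI,-82.45,44.1
MI,-83.5,45.9
MI,-85.7,45.9
MI,-86.8,43.7
MI,NA,NA
MI,-90.42,46.9
MI,-90.3,46.2
MI,-87.7,45.4
MI,-83.95,45.95
MI,-84.2,46.6
MI,-87.5,46.6
MN,-97.23,43.5
MN,-91.3,43.5
MN,-92.8,44.9
MN,-92.75,46.1
MN,-92.3,46.7
MN,-89.6,47.9
MN,-90.5,48.1
MN,-94.4,48.7
MN,-95.15,49.38
MN,-96.4,49
MN,-97.23,49
MO,-95.77,36
MO,-89.1,36
MO,-89.1,40.61
MO,-95.77,40.61
MS,-91.65,30.2
MS,-88.1,30.2
MS,-88.1,35
MS,-91.65,35
MT,-116.05,44.36
MT,-104.04,44.36
MT,-104.04,49
MT,-116.05,49
NC,-84.32,33.84
NC,-75.46,33.84
NC,-75.46,36.59
NC,-84.32,36.59
ND,-104.05,45.94
ND,-96.55,45.94
ND,-96.55,49
ND,-104.05,49
NE,-104.05,40
NE,-95.31,40
NE,-95.31,43
NE,-104.05,43
NH,-72.56,42.7
NH,-70.7,42.7
NH,-70.7,45.31
NH,-72.56,45.31
NJ,-74.95,38.93
NJ,-74.1,39.35
NJ,-73.95,40.3
NJ,-74.02,40.68
NJ,-73.92,40.99
NJ,-74.7,41.35
NJ,-75.05,41
NJ,-75.18,40.75
NJ,-74.82,40.18
NJ,-75.06,39.98
NJ,-75.18,39.8
NJ,-75.5,39.45
NJ,-75.2,39.2
NM,-109.05,31.33
NM,-103,31.33
NM,-103,37
NM,-109.05,37
NV,-120,35
NV,-114.04,35
NV,-114.04,42
NV,-120,42
NY,-79.76,42
NY,-75.35,41.99
NY,-74.7,41.36
NY,-74.02,40.64
NY,-73.75,40.55
NY,-71.85,40.75
NY,-72,41.15
NY,-73.65,40.95
NY,-73.48,41.2
NY,-73.5,42.05
NY,-73.25,42.75
NY,-73.35,43.6
NY,-73.34,45.01
NY,-74.7,45
NY,-76.2,43.5
NY,-78.9,43.3
NY,-79.1,43
NY,-79.76,42.6
OH,-84.81,39.1
OH,-83,38.7
OH,-82.35,38.45
OH,-81.56,39.3
OH,-80.73,40.1
OH,-80.52,40.64
OH,-80.52,41.98
OH,-84.82,41.7
OK,-103,36.5
OK,-103,37
OK,-94.43,37
OK,-94.43,33.62
OK,-100,33.62
OK,-100,36.5
OR,-124.57,42
OR,-116.46,42
OR,-116.46,46.26
OR,-124.57,46.26
PA,-80.52,39.72
PA,-74.7,39.72
PA,-74.7,42.27
PA,-80.52,42.27
RI,-71.89,41.3
RI,-71.12,41.3
RI,-71.12,42.02
RI,-71.89,42.02
SC,-83.35,32.05
SC,-78.54,32.05
SC,-78.54,35.21
SC,-83.35,35.21
SD,-104.06,42.49
SD,-96.44,42.49
SD,-96.44,45.94
SD,-104.06,45.94
TN,-90.31,35
TN,-81.65,35
TN,-81.65,36.68
TN,-90.31,36.68
TX,-106.65,25.84
TX,-93.51,25.84
TX,-93.51,36.5
TX,-106.65,36.5
UT,-114.05,37
UT,-109.04,37
UT,-109.04,42
UT,-114.05,42
VA,-83.65,36.6
VA,-76,36.55
VA,-76,37
VA,-76.35,37.6
VA,-76.4,38
VA,-77.05,38.7
VA,-77.5,39.02
VA,-77.73,39.3
VA,-78.35,39
VA,-79.05,38.5
VA,-79.7,38
VA,-80.3,37.4
VA,-81.3,37.25
VA,-81.95,37.5
VA,-83.2,36.9
VT,-73.44,42.73
VT,-71.46,42.73
VT,-71.46,45.01
VT,-73.44,45.01
WA,-124.76,45.54
WA,-116.92,45.54
WA,-116.92,49
WA,-124.76,49
WI,-90.64,42.5
WI,-87.8,42.5
WI,-87,43.5
WI,-87,44.5
WI,-86.95,45.3
WI,-87.8,45.35
WI,-90.12,46.34
WI,-90.9,46.95
WI,-92,46.7
WI,-92.3,46.66
WI,-92.75,46
WI,-92.8,44.9
WI,-92.77,44
WI,-91.3,43.8
WI,-91.2,43.5
WI,-91.1,43
WV,-82.6,38.4
WV,-81.75,39.34
WV,-80.67,40.1
WV,-80.52,40.64
WV,-80.52,39.72
WV,-79.48,39.72
WV,-79.48,39.2
WV,-77.75,39.32
WV,-78.35,39
WV,-79.05,38.5
WV,-79.7,38
WV,-80.3,37.4
WV,-81.4,37.25
WV,-82.3,37.35
WY,-111.05,41
WY,-104.05,41
WY,-104.05,45
WY,-111.05,45
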