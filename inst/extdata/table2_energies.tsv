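label	chain	dG_bind	ddg_printed
WTDbh	P	-2251.8	NA
WTDbh	T	-3465.7	NA
KSKIP(241-245)RVRKS	P	-2579.5	-532.2
KSKIP(241-245)RVRKS	T	-3670.2	-532.2
M76I	P	-2414.7	-380
M76I	T	-3682.8	-380
L250V	P	-2422.1	-318.3
L250V	T	-3603.7	-318.3
T37F	P	-2313.6	-159
T37F	T	-3562.9	-159
A221S	P	-2344.03	-100.45
A221S	T	-3473.91	-100.45
I62V	P	-2145.6	-60.3
I62V	T	-3632.2	-60.3
K337R	P	-2554.6	42.4
K337R	T	-3120.5	42.4
Y249I	P	-2305.0	293.6
Y249I	T	-3118.9	293.6
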