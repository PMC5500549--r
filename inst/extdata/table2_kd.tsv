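variant	kd_nM	kd_se
WTDbh	54.8	3.8
Sdbh	51.2	2.4
SdbhKSKIP(241-245)RVRKS	34.8	1.2
SdbhM76I	42.8	3.1
SdbhL250V	50.4	3.4
SdbhT37F	49.7	3.1
SdbhA221S	47.5	3.0
SdbhI62V	49.8	2.6
SdbhK337R	55.5	4.1
SdbhY249I	56.2	3.4
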