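combination	unit	good_barcode_reads	fragments	tags
PstI-MseI	1	31092630	974736	1191540
PstI-MseI	2	32074913	976575	1190301
PstI-MseI	3	32481526	978805	1203774
PstI-MseI	pool	95649069	1247742	1852830
PstI-ApeKI	1	6155700	423350	488241
PstI-ApeKI	2	14690702	562974	679210
PstI-ApeKI	3	15964678	577803	700684
PstI-ApeKI	pool	36811080	761797	1043308
EcoRI-MseI	1	8191164	351880	409007
EcoRI-MseI	2	11120572	378023	446787
EcoRI-MseI	3	13497447	385716	463467
EcoRI-MseI	pool	32809183	414294	603396
BglII-ApeKI	1	11435477	356686	425531
BglII-ApeKI	2	12485558	356658	431400
BglII-ApeKI	3	14856233	359323	452015
BglII-ApeKI	pool	38777268	436503	657868
PstI-MspI	1	10777226	313086	418533
PstI-MspI	2	11714670	321991	422068
PstI-MspI	3	12063591	322469	437846
PstI-MspI	pool	34555487	498114	788391
HinP1I-MseI	1	4208229	275611	316572
HinP1I-MseI	2	4663311	289381	323745
HinP1I-MseI	3	4786013	292617	331145
HinP1I-MseI	pool	13657553	491451	629468
HinP1I-ApeKI	1	3620005	201394	245372
HinP1I-ApeKI	2	3515377	194682	238182
HinP1I-ApeKI	3	4661900	218302	295108
HinP1I-ApeKI	pool	11797282	389479	533246
EcoRI-MspI	1	2635952	75407	93221
EcoRI-MspI	2	3086989	75537	93227
EcoRI-MspI	3	3451969	76099	96194
EcoRI-MspI	pool	9174910	96527	157425
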