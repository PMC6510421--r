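cohort	arm	n	events_chd	events_mi
KORA	discovery	3788	NA	109
GENOA	discovery	417	77	NA
ARIC	discovery	8815	1625	859
CHS	discovery	2939	942	498
GeneSTAR	discovery	594	85	30
FHS	discovery	1828	305	158
RS	discovery	834	113	57
MESA	replication	2506	128	62
WGHS	replication	27553	1035	413
LURIC	replication	921	59	NA
SHIP	replication	3229	260	212
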