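female	male	female_taxon	male_taxon	n_spikelets	n_seeds
ID396	ID1277	T._m._monococcum	T._urartu	100	0
L118	ID388	T._m._monococcum	T._urartu	700	33
ID752	ID1122	T._m._boeoticum	T._urartu	274	14
ID752	ID1277	T._m._boeoticum	T._urartu	200	11
ID752	ID1391	T._m._boeoticum	T._urartu	200	7
ID752	ID393	T._m._boeoticum	T._urartu	373	10
ID758	ID1122	T._m._boeoticum	T._urartu	600	6
ID758	ID1264	T._m._boeoticum	T._urartu	200	1
ID758	ID1277	T._m._boeoticum	T._urartu	562	2
ID1391	ID396	T._urartu	T._m._monococcum	100	7
ID1122	ID752	T._urartu	T._m._boeoticum	58	0
ID1391	ID758	T._urartu	T._m._boeoticum	100	0
ID393	ID752	T._urartu	T._m._boeoticum	500	0
ID1264	ID752	T._urartu	T._m._boeoticum	338	2
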