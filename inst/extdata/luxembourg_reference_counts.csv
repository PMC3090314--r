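year,initial_population,treated_diabetes,treated_type2
,484560,22178,21068
2000,418182,13416,13152
2001,424037,14277,13944
2002,428457,14956,14704
2003,433424,15489,15269
2004,439628,16241,16026
2005,444783,17172,16751
2006,450000,17522,17070
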