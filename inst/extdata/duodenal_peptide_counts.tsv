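substrate	time_min	total	common
casein	5	444	270
casein	10	369	170
casein	15	312	140
casein	20	419	211
casein	30	303	145
casein	45	312	148
casein	60	418	221
casein	90	427	187
casein	120	425	222
casein	150	434	217
hydrolysate	5	258	98
hydrolysate	10	294	115
hydrolysate	15	237	91
hydrolysate	20	281	137
hydrolysate	30	299	140
hydrolysate	45	274	137
hydrolysate	60	283	142
hydrolysate	90	290	136
hydrolysate	120	338	158
hydrolysate	150	258	137
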