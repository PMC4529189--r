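template	t1	t2	t3	t4	t5	t6	t7
rise_linear	0	1	2	3	4	5	6
fall_linear	6	5	4	3	2	1	0
spike_early	0	6	1	0	0	0	0
spike_late	0	0	0	0	6	0	0
rise_late	0	0	0	0	0	0	6
hump_mid	0	1	5	6	5	1	0
valley_broad	6	3	0	0	1	3	6
rise_plateau	0	6	6	6	6	6	6
fall_early	6	1	0	0	0	0	0
spike_decay	0	6	6	4	3	1	0
osc_up	0	4	0	4	0	4	0
osc_down	4	0	4	0	4	0	4
up_down_up	0	5	2	0	2	5	6
plateau_fall	6	6	6	6	6	6	0
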