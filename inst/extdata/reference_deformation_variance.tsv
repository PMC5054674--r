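pc	eigenvalue	variance_pct	cumulative_pct
1	7667.726	62.504	62.504
2	612.476	4.993	67.496
3	469.388	3.826	71.322
4	404.313	3.296	74.618
5	304.468	2.482	77.100
6	288.151	2.349	79.449
7	265.016	2.160	81.609
8	230.903	1.882	83.491
9	162.446	1.324	84.816
10	155.662	1.269	86.085
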