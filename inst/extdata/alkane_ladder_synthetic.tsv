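carbon_number	retention_time_min
8	4.2000
9	5.3500
10	6.4500
11	7.5200
12	8.5600
13	9.5800
14	10.5800
15	11.5600
16	12.5200
17	13.4600
18	14.3800
19	15.2800
20	16.1600
21	17.0200
22	17.8600
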