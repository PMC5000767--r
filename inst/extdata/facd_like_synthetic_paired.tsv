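conformation_id	time_ns	barrier_small	barrier_big
t1	0.5	24.9408227456777	19.4908344857236
t2	1	20.5472373791776	14.2115886236725
t3	1.5	26.0991971114979	21.777507273513
t4	2	17.8844349832831	12.7440208423216
t5	2.5	21.0461129941836	14.4836017113842
t6	3	25.2858357055564	15.865069675473
t7	3.5	14.7001107931959	7.31476119773607
t8	4	20.9287591782404	12.2640688714583
t9	4.5	23.5982611839417	11.8477257680486
t10	5	21.1762823164244	13.7506172122614
t11	5.5	22.1956395917172	15.6929770568398
t12	6	19.7364808958799	17.4316457435147
t13	6.5	18.4546121376306	16.0707623321782
t14	7	24.3719444861983	20.9477515965287
t15	7.5	19.0671482424946	10.5171562282934
t16	8	22.9519627808816	12.6283058088485
t17	8.5	25.7459676422546	17.6230022440567
t18	9	20.630839681689	17.5252802732969
t19	9.5	21.6606602310926	15.8648161477506
t20	10	22.5844723549683	17.5685553511382
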