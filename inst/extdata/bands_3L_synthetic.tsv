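band	start_bp	end_bp
61A	0	192000
61B	192000	384000
61C	384000	576000
61D	576000	768000
61E	768000	960000
61F	960000	1152000
62A	1152000	1344000
62B	1344000	1536000
62C	1536000	1728000
62D	1728000	1920000
62E	1920000	2112000
62F	2112000	2304000
63A	2304000	2496000
63B	2496000	2688000
63C	2688000	2880000
63D	2880000	3072000
63E	3072000	3264000
63F	3264000	3456000
64A	3456000	3648000
64B	3648000	3840000
64C	3840000	4032000
64D	4032000	4224000
64E	4224000	4416000
64F	4416000	4608000
65A	4608000	4800000
65B	4800000	4992000
65C	4992000	5184000
65D	5184000	5376000
65E	5376000	5568000
65F	5568000	5760000
66A	5760000	5952000
66B	5952000	6144000
66C	6144000	6336000
66D	6336000	6528000
66E	6528000	6720000
66F	6720000	6912000
67A	6912000	7104000
67B	7104000	7296000
67C	7296000	7488000
67D	7488000	7680000
67E	7680000	7872000
67F	7872000	8064000
68A	8064000	8256000
68B	8256000	8448000
68C	8448000	8640000
68D	8640000	8832000
68E	8832000	9024000
68F	9024000	9216000
69A	9216000	9408000
69B	9408000	9600000
69C	9600000	9792000
69D	9792000	9984000
69E	9984000	10176000
69F	10176000	10368000
70A	10368000	10560000
70B	10560000	10752000
70C	10752000	10944000
70D	10944000	11136000
70E	11136000	11328000
70F	11328000	11520000
71A	11520000	11712000
71B	11712000	11904000
71C	11904000	12096000
71D	12096000	12288000
71E	12288000	12480000
71F	12480000	12672000
72A	12672000	12864000
72B	12864000	13056000
72C	13056000	13248000
72D	13248000	13440000
72E	13440000	13632000
72F	13632000	13824000
73A	13824000	14016000
73B	14016000	14208000
73C	14208000	14400000
73D	14400000	14592000
73E	14592000	14784000
73F	14784000	14976000
74A	14976000	15168000
74B	15168000	15360000
74C	15360000	15552000
74D	15552000	15744000
74E	15744000	15936000
74F	15936000	16128000
75A	16128000	16320000
75B	16320000	16512000
75C	16512000	16704000
75D	16704000	16896000
75E	16896000	17088000
75F	17088000	17280000
76A	17280000	17472000
76B	17472000	17664000
76C	17664000	17856000
76D	17856000	18048000
76E	18048000	18240000
76F	18240000	18432000
77A	18432000	18624000
77B	18624000	18816000
77C	18816000	19008000
77D	19008000	19200000
77E	19200000	19392000
77F	19392000	19584000
78A	19584000	19776000
78B	19776000	19968000
78C	19968000	20160000
78D	20160000	20352000
78E	20352000	20544000
78F	20544000	20736000
79A	20736000	20928000
79B	20928000	21120000
79C	21120000	21312000
79D	21312000	21504000
79E	21504000	21696000
79F	21696000	21888000
80A	21888000	22080000
80B	22080000	22272000
80C	22272000	22464000
80D	22464000	22656000
80E	22656000	22848000
80F	22848000	23040000
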