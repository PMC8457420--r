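# animal_id: fixture12
# group: EYFP_CONTROL
# day: 1
# protocol: NONE
time_s	code	payload
0.00	BLOCK_SELF_START
1.00	BEAM_OUT
2.00	LP1
2.50	LP1
3.00	LP1
3.50	LP1
4.50	LP2
5.00	LP2
5.50	LP2
6.00	LP2
6.00	REWARD
7.00	MAG_IN
20.00	BEAM_OUT
21.00	LP1
21.40	LP1
22.40	LP2
23.40	MAG_IN
23.41	TIMEOUT_START
40.00	BEAM_OUT
41.00	LP1
41.50	LP1
42.00	LP1
42.50	LP1
43.00	LP1
44.00	LP2
44.40	LP2
44.80	LP2
45.20	LP2
45.20	REWARD
46.20	MAG_IN
60.00	BEAM_OUT
61.50	LP2
62.00	LP2
63.00	MAG_IN
63.01	TIMEOUT_START
80.00	BEAM_OUT
81.00	LP1
81.50	LP1
82.00	LP1
83.50	MAG_IN
83.51	TIMEOUT_START
100.00	BEAM_OUT
101.00	LP1
101.50	LP1
102.00	LP1
102.50	LP1
104.00	LP2
104.50	LP2
106.00	MAG_IN
106.01	TIMEOUT_START
120.00	BEAM_OUT
121.00	MAG_IN
122.00	BEAM_OUT
123.00	LP1
123.50	LP1
124.00	LP1
124.50	LP1
125.50	LP2
126.00	LP2
126.50	LP2
127.00	LP2
127.00	REWARD
128.00	MAG_IN
140.00	BEAM_OUT
140.00	LP1
140.50	LP1
141.00	LP1
141.50	LP1
143.00	LP2
143.40	LP2
143.80	LP2
144.20	LP2
144.20	REWARD
145.20	MAG_IN
160.00	BEAM_OUT
161.00	LP1
161.50	LP1
162.50	LP2
163.00	LP1
163.50	LP2
164.50	MAG_IN
164.51	TIMEOUT_START
180.00	BLOCK_FORCED_START
181.00	BEAM_OUT
182.00	LP1
182.50	LP1
183.00	LP1
183.50	LP1
185.00	LP2
185.50	LP2
186.00	LP2
186.50	LP2
186.50	REWARD
187.50	MAG_IN
200.00	BEAM_OUT
201.00	LP1
201.50	LP1
203.00	MAG_IN
203.01	TIMEOUT_START
220.00	BEAM_OUT
221.00	LP1
221.50	LP1
222.00	LP1
222.50	LP1
224.00	MAG_IN
224.01	TIMEOUT_START
240.00	BEAM_OUT
241.00	LP1
241.30	LP1
241.60	LP1
241.90	LP1
243.00	LP2
243.30	LP2
243.60	LP2
243.90	LP2
243.90	REWARD
245.00	MAG_IN
250.00	SESSION_END
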