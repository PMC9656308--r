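"r","g","b"
255,255,255
255,255,255
255,255,252
255,255,252
255,255,249
255,255,249
255,255,246
255,255,246
255,255,243
255,255,243
255,255,240
255,255,240
255,255,237
255,255,237
255,255,234
255,255,234
255,255,231
255,255,231
255,255,228
255,255,228
255,255,225
255,255,225
255,255,222
255,255,222
255,255,219
255,255,219
255,255,216
255,255,216
255,255,213
255,255,213
255,255,210
255,255,210
255,255,207
255,255,207
255,255,204
255,255,204
255,255,201
255,255,201
255,255,198
255,255,198
255,255,195
255,255,195
255,255,192
255,255,192
255,255,189
255,255,189
255,255,186
255,255,186
255,255,183
255,255,183
255,255,180
255,255,180
255,255,177
255,255,177
255,255,174
255,255,174
255,255,171
255,255,171
255,255,168
255,255,168
255,255,165
255,255,165
255,255,162
255,255,162
255,255,159
255,255,159
255,255,156
255,255,156
255,255,153
255,255,153
255,255,150
255,255,150
255,255,147
255,255,147
255,255,144
255,255,144
255,255,141
255,255,141
255,255,138
255,255,138
255,255,135
255,255,135
255,255,132
255,255,132
255,255,129
255,255,129
255,255,126
255,255,126
255,255,123
255,255,123
255,255,120
255,255,120
255,255,117
255,255,117
255,255,114
255,255,114
255,255,111
255,255,111
255,255,108
255,255,108
255,255,105
255,255,105
255,255,102
255,255,102
255,255,99
255,255,99
255,255,96
255,255,96
255,255,93
255,255,93
255,255,90
255,255,90
255,255,87
255,255,87
255,255,84
255,255,84
255,255,81
255,255,81
255,255,78
255,255,78
255,255,75
255,255,75
255,255,72
255,255,72
255,255,69
255,255,69
255,255,66
255,255,66
255,255,63
255,255,63
255,255,60
255,255,60
255,255,57
255,255,57
255,255,54
255,255,54
255,255,51
255,255,51
255,255,48
255,255,48
255,255,45
255,255,45
255,255,42
255,255,42
255,255,39
255,255,39
255,255,36
255,255,36
255,255,33
255,255,33
255,255,30
255,255,30
255,255,27
255,255,27
255,255,24
255,255,24
255,255,21
255,255,21
255,255,18
255,255,18
255,255,15
255,255,15
255,255,12
255,255,12
255,255,9
255,255,9
255,255,6
255,255,6
255,255,3
255,255,3
255,255,0
255,255,0
255,252,0
255,252,0
255,249,0
255,249,0
255,246,0
255,246,0
255,243,0
255,243,0
255,240,0
255,240,0
255,237,0
255,237,0
255,234,0
255,234,0
255,231,0
255,231,0
255,228,0
255,228,0
255,225,0
255,225,0
255,222,0
255,222,0
255,219,0
255,219,0
255,216,0
255,216,0
255,213,0
255,213,0
255,210,0
255,210,0
255,207,0
255,207,0
255,204,0
255,204,0
255,201,0
255,201,0
255,198,0
255,198,0
255,195,0
255,195,0
255,192,0
255,192,0
255,189,0
255,189,0
255,186,0
255,186,0
255,183,0
255,183,0
255,180,0
255,180,0
255,177,0
255,177,0
255,174,0
255,174,0
255,171,0
255,171,0
255,168,0
255,168,0
255,165,0
255,165,0
255,162,0
255,162,0
255,159,0
255,159,0
255,156,0
255,156,0
255,153,0
255,153,0
255,150,0
255,150,0
255,147,0
255,147,0
255,144,0
255,144,0
255,141,0
255,141,0
255,138,0
255,138,0
255,135,0
255,135,0
255,132,0
255,132,0
255,129,0
255,129,0
255,126,0
255,126,0
255,123,0
255,123,0
255,120,0
255,120,0
255,117,0
255,117,0
255,114,0
255,114,0
255,111,0
255,111,0
255,108,0
255,108,0
255,105,0
255,105,0
255,102,0
255,102,0
255,99,0
255,99,0
255,96,0
255,96,0
255,93,0
255,93,0
255,90,0
255,90,0
255,87,0
255,87,0
255,84,0
255,84,0
255,81,0
255,81,0
255,78,0
255,78,0
255,75,0
255,75,0
255,72,0
255,72,0
255,69,0
255,69,0
255,66,0
255,66,0
255,63,0
255,63,0
255,60,0
255,60,0
255,57,0
255,57,0
255,54,0
255,54,0
255,51,0
255,51,0
255,48,0
255,48,0
255,45,0
255,45,0
255,42,0
255,42,0
255,39,0
255,39,0
255,36,0
255,36,0
255,33,0
255,33,0
255,30,0
255,30,0
255,27,0
255,27,0
255,24,0
255,24,0
255,21,0
255,21,0
255,18,0
255,18,0
255,15,0
255,15,0
255,12,0
255,12,0
255,9,0
255,9,0
255,6,0
255,6,0
255,3,0
255,3,0
255,0,0
255,0,0
252,0,0
252,0,0
249,0,0
249,0,0
246,0,0
246,0,0
243,0,0
243,0,0
240,0,0
240,0,0
237,0,0
237,0,0
234,0,0
234,0,0
231,0,0
231,0,0
228,0,0
228,0,0
225,0,0
225,0,0
222,0,0
222,0,0
219,0,0
219,0,0
216,0,0
216,0,0
213,0,0
213,0,0
210,0,0
210,0,0
207,0,0
207,0,0
204,0,0
204,0,0
201,0,0
201,0,0
198,0,0
198,0,0
195,0,0
195,0,0
192,0,0
192,0,0
189,0,0
189,0,0
186,0,0
186,0,0
183,0,0
183,0,0
180,0,0
180,0,0
177,0,0
177,0,0
174,0,0
174,0,0
171,0,0
171,0,0
168,0,0
168,0,0
165,0,0
165,0,0
162,0,0
162,0,0
159,0,0
159,0,0
156,0,0
156,0,0
153,0,0
153,0,0
150,0,0
150,0,0
147,0,0
147,0,0
144,0,0
144,0,0
141,0,0
141,0,0
138,0,0
138,0,0
135,0,0
135,0,0
132,0,0
132,0,0
129,0,0
129,0,0
126,0,0
126,0,0
123,0,0
123,0,0
120,0,0
120,0,0
117,0,0
117,0,0
114,0,0
114,0,0
111,0,0
111,0,0
108,0,0
108,0,0
105,0,0
105,0,0
102,0,0
102,0,0
99,0,0
99,0,0
96,0,0
96,0,0
93,0,0
93,0,0
90,0,0
90,0,0
87,0,0
87,0,0
84,0,0
84,0,0
81,0,0
81,0,0
78,0,0
78,0,0
75,0,0
75,0,0
72,0,0
72,0,0
69,0,0
69,0,0
66,0,0
66,0,0
63,0,0
63,0,0
60,0,0
60,0,0
57,0,0
57,0,0
54,0,0
54,0,0
51,0,0
51,0,0
48,0,0
48,0,0
45,0,0
45,0,0
42,0,0
42,0,0
39,0,0
39,0,0
36,0,0
36,0,0
33,0,0
33,0,0
30,0,0
30,0,0
27,0,0
27,0,0
24,0,0
24,0,0
21,0,0
21,0,0
18,0,0
18,0,0
15,0,0
15,0,0
12,0,0
12,0,0
9,0,0
9,0,0
6,0,0
6,0,0
3,0,0
3,0,0
0,0,0
0,0,0
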