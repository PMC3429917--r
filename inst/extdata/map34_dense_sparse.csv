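marker,chromosome,position_cM
m01,1,0
m02,1,2
m03,1,4
m04,1,6
m05,1,8
m06,1,10
m07,1,12
m08,1,14
m09,1,16
m10,1,18
m11,1,38
m12,1,58
m13,1,78
m14,1,98
m15,1,118
m16,1,138
m17,1,158
m18,1,160
m19,1,162
m20,1,164
m21,1,166
m22,1,168
m23,1,170
m24,1,172
m25,1,174
m26,1,176
m27,1,178
m28,1,198
m29,1,218
m30,1,238
m31,1,258
m32,1,278
m33,1,298
m34,1,318
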