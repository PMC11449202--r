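"bat_id","night_index","tree_id","duration","flyover"
"jun_G_N01",1,1,540,FALSE
"jun_G_N02",1,2,540,FALSE
"jun_G_N03",1,1,540,FALSE
"jun_G_N04",2,2,540,FALSE
"jun_G_M01",1,2,540,FALSE
"jun_G_M02",2,1,540,FALSE
"jun_Z_N01",2,1,540,FALSE
"jun_Z_N02",3,2,540,FALSE
"jun_Z_M01",3,2,540,FALSE
"dec_G_N01",171,1,540,FALSE
"dec_G_N02",172,2,540,FALSE
"dec_G_M01",172,2,540,FALSE
"dec_Z_N01",172,1,540,FALSE
"jul_G_N01",33,1,540,FALSE
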