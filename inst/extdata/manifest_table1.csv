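"bat_id","roost","role","night"
"jun_G_M01","Gershom","manipulated",0
"jun_G_M02","Gershom","manipulated",0
"jun_G_M03","Gershom","manipulated",0
"jun_G_N01","Gershom","naive",0
"jun_G_N02","Gershom","naive",0
"jun_G_N03","Gershom","naive",0
"jun_G_N04","Gershom","naive",0
"jun_G_N05","Gershom","naive",0
"jun_G_N06","Gershom","naive",0
"jun_G_N07","Gershom","naive",0
"jun_G_N08","Gershom","naive",0
"jun_G_N09","Gershom","naive",0
"jun_Z_M01","Zemer","manipulated",0
"jun_Z_M02","Zemer","manipulated",0
"jun_Z_M03","Zemer","manipulated",0
"jun_Z_M04","Zemer","manipulated",0
"jun_Z_N01","Zemer","naive",0
"jun_Z_N02","Zemer","naive",0
"jun_Z_N03","Zemer","naive",0
"jun_Z_N04","Zemer","naive",0
"jun_Z_N05","Zemer","naive",0
"jun_Z_N06","Zemer","naive",0
"dec_G_M01","Gershom","manipulated",168
"dec_G_M02","Gershom","manipulated",168
"dec_G_M03","Gershom","manipulated",168
"dec_G_M04","Gershom","manipulated",168
"dec_G_N01","Gershom","naive",168
"dec_G_N02","Gershom","naive",168
"dec_G_N03","Gershom","naive",168
"dec_G_N04","Gershom","naive",168
"dec_G_N05","Gershom","naive",168
"dec_G_N06","Gershom","naive",168
"dec_G_N07","Gershom","naive",168
"dec_G_N08","Gershom","naive",168
"dec_G_N09","Gershom","naive",168
"dec_G_N10","Gershom","naive",168
"dec_G_N11","Gershom","naive",168
"dec_G_N12","Gershom","naive",168
"dec_G_N13","Gershom","naive",168
"dec_G_N14","Gershom","naive",168
"dec_G_N15","Gershom","naive",168
"dec_Z_M01","Zemer","manipulated",168
"dec_Z_N01","Zemer","naive",168
"dec_Z_N02","Zemer","naive",168
"dec_Z_N03","Zemer","naive",168
"dec_Z_N04","Zemer","naive",168
"dec_Z_N05","Zemer","naive",168
"dec_Z_N06","Zemer","naive",168
"dec_Z_N07","Zemer","naive",168
"jul_G_M01","Gershom","manipulated",27
"jul_G_M02","Gershom","manipulated",27
"jul_G_M03","Gershom","manipulated",27
"jul_G_M04","Gershom","manipulated",27
"jul_G_N01","Gershom","naive",27
"jul_G_N02","Gershom","naive",27
"jul_G_N03","Gershom","naive",27
"jul_G_N04","Gershom","naive",27
"jul_G_N05","Gershom","naive",27
"jul_G_N06","Gershom","naive",27
"jul_G_N07","Gershom","naive",27
"jul_G_N08","Gershom","naive",27
"jul_G_N09","Gershom","naive",27
"jul_G_N10","Gershom","naive",27
"jul_G_N11","Gershom","naive",27
"jul_G_N12","Gershom","naive",27
"jul_G_N13","Gershom","naive",27
"jul_G_N14","Gershom","naive",27
"jul_G_N15","Gershom","naive",27
"jul_G_N16","Gershom","naive",27
"jul_G_N17","Gershom","naive",27
"jul_G_N18","Gershom","naive",27
"jul_G_N19","Gershom","naive",27
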