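analyte_id,group,n,n_detected,mean,sd,median,max,convention
irganox_1010,PLA,10,2,0.3529,0.8817,0,2.7684,nd_as_zero
irganox_1010,starch,15,11,0.5305,0.638,0.2033,1.7218,nd_as_zero
irganox_1010,fiber,14,0,0,0,0,0,nd_as_zero
irganox_1010,total,39,13,0.2945,0.6237,0,2.7684,nd_as_zero
irgafos_168,PLA,10,3,0.4234,1.3388,0,4.2335,nd_as_zero
irgafos_168,starch,15,9,0.39,0.4486,0.235,1.3234,nd_as_zero
irgafos_168,fiber,14,0,0,0,0,0,nd_as_zero
irgafos_168,total,39,12,0.2586,0.733,0,4.2335,nd_as_zero
irganox_1076,PLA,10,5,0.0468,0.0771,0.0015,0.227,nd_as_zero
irganox_1076,starch,15,11,0.1322,0.1568,0.0464,0.4366,nd_as_zero
irganox_1076,fiber,14,0,0,0,0,0,nd_as_zero
irganox_1076,total,39,16,0.0628,0.1179,0,0.4366,nd_as_zero
dtbp_24,PLA,10,1,0.0371,0.1173,0,0.3708,nd_as_zero
dtbp_24,starch,15,4,0.0273,0.0719,0,0.2287,nd_as_zero
dtbp_24,fiber,14,0,0,0,0,0,nd_as_zero
dtbp_24,total,39,5,0.02,0.0735,0,0.3708,nd_as_zero
antioxidant_dltp,PLA,10,1,0.0674,0.2132,0,0.6741,nd_as_zero
antioxidant_dltp,starch,15,0,0,0,0,0,nd_as_zero
antioxidant_dltp,fiber,14,0,0,0,0,0,nd_as_zero
antioxidant_dltp,total,39,1,0.0173,0.1079,0,0.6741,nd_as_zero
irganox_1310,PLA,10,2,0.0073,0.0214,0,0.0681,nd_as_zero
irganox_1310,starch,15,14,0.0185,0.0152,0.0168,0.0435,nd_as_zero
irganox_1310,fiber,14,0,0,0,0,0,nd_as_zero
irganox_1310,total,39,16,0.009,0.0161,0,0.0681,nd_as_zero
antioxidant_jx35,PLA,10,1,0.0011,0.0036,0,0.0114,nd_as_zero
antioxidant_jx35,starch,15,11,0.014,0.0172,0.0077,0.0597,nd_as_zero
antioxidant_jx35,fiber,14,0,0,0,0,0,nd_as_zero
antioxidant_jx35,total,39,12,0.0057,0.0125,0,0.0597,nd_as_zero
irganox_3114,PLA,10,0,0,0,0,0,nd_as_zero
irganox_3114,starch,15,3,0.0029,0.0068,0,0.0238,nd_as_zero
irganox_3114,fiber,14,0,0,0,0,0,nd_as_zero
irganox_3114,total,39,3,0.0011,0.004,0,0.0238,nd_as_zero
irganox_330,PLA,10,0,0,0,0,0,nd_as_zero
irganox_330,starch,15,2,0.0003,0.0008,0,0.0028,nd_as_zero
irganox_330,fiber,14,0,0,0,0,0,nd_as_zero
irganox_330,total,39,2,0.0001,0.0005,0,0.0028,nd_as_zero
irganox_245,PLA,10,0,0,0,0,0,nd_as_zero
irganox_245,starch,15,1,0.00004,0.0002,0,0.0006,nd_as_zero
irganox_245,fiber,14,0,0,0,0,0,nd_as_zero
irganox_245,total,39,1,0.00002,0.00001,0,0.0006,nd_as_zero
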