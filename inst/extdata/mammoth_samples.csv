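sample_id,age_cal_bp,age_is_bound,material,region
L267,49000,TRUE,Tusk,Chukotka
L272,47400,TRUE,Tusk,Chukotka
L155,47772,FALSE,Tooth,Chukotka
L156,49466,FALSE,Femur,Chukotka
M2,38000,TRUE,Tooth,Wrangel
L163,30525,FALSE,Tusk,Chukotka
L152,23891,FALSE,Tooth,Chukotka
M6,24063,FALSE,Tooth,Wrangel
M7,21846,FALSE,Bone,Wrangel
L164,16901,FALSE,Tusk,Chukotka
L158,14431,FALSE,Humerus,Chukotka
M9,13872,FALSE,Tooth,Wrangel
M17,8318,FALSE,Tooth,Wrangel Island
M23,7470,FALSE,Tusk,Wrangel Island
M28,6380,FALSE,Tusk,Wrangel Island
L385,6074,FALSE,Tooth,Wrangel Island
L387,5601,FALSE,Tooth,Wrangel Island
M32,5131,FALSE,Tooth,Wrangel Island
E460,4969,FALSE,Tusk,Wrangel Island
E461,4959,FALSE,Bone,Wrangel Island
M38,4726,FALSE,Tooth,Wrangel Island
E466,4354,FALSE,Tusk,Wrangel Island
M42,4336,FALSE,Tooth,Wrangel Island
E468,4079,FALSE,Tusk,Wrangel Island
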