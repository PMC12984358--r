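sample_id,material_class,product_type,medium,temperature_c,duration_h,analyte_id,concentration_mg_per_kg,censored,lod,loq
no_01,PLA,meal_box,soybean_oil,70,2,irganox_1310,,TRUE,0.00021,0.0007
no_03,PLA,meal_box,soybean_oil,70,2,irganox_1310,,TRUE,0.00021,0.0007
no_15,starch,meal_box,soybean_oil,70,2,irganox_1310,,TRUE,0.00021,0.0007
no_16,starch,meal_box,soybean_oil,70,2,irganox_1310,,TRUE,0.00021,0.0007
no_19,starch,plate,soybean_oil,70,2,irganox_1310,0.0094,FALSE,0.00021,0.0007
no_20,starch,plate,soybean_oil,70,2,irganox_1310,,TRUE,0.00021,0.0007
no_21,starch,bowl,soybean_oil,70,2,irganox_1310,,TRUE,0.00021,0.0007
no_22,starch,cutlery,soybean_oil,70,2,irganox_1310,,TRUE,0.00021,0.0007
no_01,PLA,meal_box,soybean_oil,70,2,antioxidant_jx35,0.0188,FALSE,0.00001,0.00005
no_03,PLA,meal_box,soybean_oil,70,2,antioxidant_jx35,,TRUE,0.00001,0.00005
no_15,starch,meal_box,soybean_oil,70,2,antioxidant_jx35,0.0137,FALSE,0.00001,0.00005
no_16,starch,meal_box,soybean_oil,70,2,antioxidant_jx35,0.0195,FALSE,0.00001,0.00005
no_19,starch,plate,soybean_oil,70,2,antioxidant_jx35,0.0254,FALSE,0.00001,0.00005
no_20,starch,plate,soybean_oil,70,2,antioxidant_jx35,0.0062,FALSE,0.00001,0.00005
no_21,starch,bowl,soybean_oil,70,2,antioxidant_jx35,0.0061,FALSE,0.00001,0.00005
no_22,starch,cutlery,soybean_oil,70,2,antioxidant_jx35,0.0049,FALSE,0.00001,0.00005
no_01,PLA,meal_box,soybean_oil,70,2,irganox_1076,,TRUE,0.0015,0.00501
no_03,PLA,meal_box,soybean_oil,70,2,irganox_1076,,TRUE,0.0015,0.00501
no_15,starch,meal_box,soybean_oil,70,2,irganox_1076,,TRUE,0.0015,0.00501
no_16,starch,meal_box,soybean_oil,70,2,irganox_1076,,TRUE,0.0015,0.00501
no_19,starch,plate,soybean_oil,70,2,irganox_1076,0.3965,FALSE,0.0015,0.00501
no_20,starch,plate,soybean_oil,70,2,irganox_1076,,TRUE,0.0015,0.00501
no_21,starch,bowl,soybean_oil,70,2,irganox_1076,,TRUE,0.0015,0.00501
no_22,starch,cutlery,soybean_oil,70,2,irganox_1076,,TRUE,0.0015,0.00501
no_01,PLA,meal_box,soybean_oil,70,2,irgafos_168,,TRUE,0.00014,0.00046
no_03,PLA,meal_box,soybean_oil,70,2,irgafos_168,,TRUE,0.00014,0.00046
no_15,starch,meal_box,soybean_oil,70,2,irgafos_168,,TRUE,0.00014,0.00046
no_16,starch,meal_box,soybean_oil,70,2,irgafos_168,,TRUE,0.00014,0.00046
no_19,starch,plate,soybean_oil,70,2,irgafos_168,,TRUE,0.00014,0.00046
no_20,starch,plate,soybean_oil,70,2,irgafos_168,,TRUE,0.00014,0.00046
no_21,starch,bowl,soybean_oil,70,2,irgafos_168,,TRUE,0.00014,0.00046
no_22,starch,cutlery,soybean_oil,70,2,irgafos_168,,TRUE,0.00014,0.00046
no_01,PLA,meal_box,soybean_oil,70,2,irganox_1010,0.3286,FALSE,0.00008,0.00027
no_03,PLA,meal_box,soybean_oil,70,2,irganox_1010,,TRUE,0.00008,0.00027
no_15,starch,meal_box,soybean_oil,70,2,irganox_1010,0.2217,FALSE,0.00008,0.00027
no_16,starch,meal_box,soybean_oil,70,2,irganox_1010,0.0539,FALSE,0.00008,0.00027
no_19,starch,plate,soybean_oil,70,2,irganox_1010,0.6037,FALSE,0.00008,0.00027
no_20,starch,plate,soybean_oil,70,2,irganox_1010,0.3792,FALSE,0.00008,0.00027
no_21,starch,bowl,soybean_oil,70,2,irganox_1010,0.2592,FALSE,0.00008,0.00027
no_22,starch,cutlery,soybean_oil,70,2,irganox_1010,0.5557,FALSE,0.00008,0.00027
no_01,PLA,meal_box,soybean_oil,70,2,dtbp_24,,TRUE,0.00377,0.01257
no_03,PLA,meal_box,soybean_oil,70,2,dtbp_24,,TRUE,0.00377,0.01257
no_15,starch,meal_box,soybean_oil,70,2,dtbp_24,,TRUE,0.00377,0.01257
no_16,starch,meal_box,soybean_oil,70,2,dtbp_24,,TRUE,0.00377,0.01257
no_19,starch,plate,soybean_oil,70,2,dtbp_24,,TRUE,0.00377,0.01257
no_20,starch,plate,soybean_oil,70,2,dtbp_24,,TRUE,0.00377,0.01257
no_21,starch,bowl,soybean_oil,70,2,dtbp_24,,TRUE,0.00377,0.01257
no_22,starch,cutlery,soybean_oil,70,2,dtbp_24,,TRUE,0.00377,0.01257
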