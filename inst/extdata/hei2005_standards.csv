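component,orientation,max_points,numerator,basis,scale,standard,mid_value,mid_points,zero_value
total_fruit,adequacy,5,total_fruit,per1000,1,0.8,NA,NA,NA
whole_fruit,adequacy,5,whole_fruit,per1000,1,0.4,NA,NA,NA
total_vegetables,adequacy,5,total_vegetables,per1000,1,1.1,NA,NA,NA
dark_green_orange_veg_legumes,adequacy,5,dark_green_orange_veg,per1000,1,0.4,NA,NA,NA
total_grains,adequacy,5,total_grains,per1000,1,3.0,NA,NA,NA
whole_grains,adequacy,5,whole_grains,per1000,1,1.5,NA,NA,NA
milk,adequacy,10,milk,per1000,1,1.3,NA,NA,NA
meat_beans,adequacy,10,meat_beans,per1000,1,2.5,NA,NA,NA
oils,adequacy,10,oils,per1000,1,12,NA,NA,NA
saturated_fat,moderation,10,saturated_fat,pct_energy,9,7,10,8,15
sodium,moderation,10,sodium,per1000,0.001,0.7,1.1,8,2.0
sofaas,moderation,20,sofaas_energy,pct_energy,1,20,NA,NA,50
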