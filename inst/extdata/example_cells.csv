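experiment_id,animal_id,ring,cell_id,nucleus_count,ch_green,ch_red
exp1,exp1_an01,1,int1a,2,1000.2636142735303,437.34987355565744
exp1,exp1_an01,1,int1b,2,1583.6628298573169,504.3052558964423
exp1,exp1_an01,2,int2a,2,582.42504947184113,506.82789709247896
exp1,exp1_an01,2,int2b,2,958.42602170975908,703.96712851731206
exp1,exp1_an01,3,int3a,2,438.32896283881053,393.11312375370085
exp1,exp1_an01,3,int3b,2,921.83641863922549,893.48612091999632
exp1,exp1_an01,4,int4a,2,557.27028183264599,609.69489110256814
exp1,exp1_an01,4,int4b,2,596.21868345214136,1007.4394354829953
exp1,exp1_an02,1,int1a,2,589.86884502897044,285.17559800190043
exp1,exp1_an02,1,int1b,2,1089.8241590612454,388.00372870457016
exp1,exp1_an02,2,int2a,2,666.24421838803664,367.34779617567091
exp1,exp1_an02,2,int2b,2,917.13638887777552,485.38400875350726
exp1,exp1_an02,3,int3a,2,434.58979440076035,305.80818671071199
exp1,exp1_an02,3,int3b,2,723.54566624538143,881.87312300126473
exp1,exp1_an02,4,int4a,2,540.72239855230453,760.54535141636313
exp1,exp1_an02,4,int4b,2,381.63546950243608,471.34820134615131
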