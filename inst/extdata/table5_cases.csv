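factor,stratum,level,count
age_band,all,0-2,13
age_band,all,3-6,24
age_band,all,7-11,4
sex,all,male,22
sex,all,female,19
gestational_age,all,<37,4
gestational_age,all,>=37,37
birth_weight,all,<2500,10
birth_weight,all,>=2500,31
co_sleeping,0-2,yes,12
co_sleeping,0-2,no,1
co_sleeping,3-6,yes,17
co_sleeping,3-6,no,7
co_sleeping,7-11,yes,3
co_sleeping,7-11,no,1
sleep_position,all,prone,19
sleep_position,all,not_prone,22
breastfeeding,0-2,yes,11
breastfeeding,0-2,no,2
breastfeeding,3-6,yes,7
breastfeeding,3-6,no,17
breastfeeding,7-11,yes,3
breastfeeding,7-11,no,1
passive_smoking,all,yes,21
passive_smoking,all,no,9
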