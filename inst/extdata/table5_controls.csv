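factor,stratum,level,count,proportion,source
age_band,all,0-2,3,,uniform-by-month convention (3 of 12 months)
age_band,all,3-6,4,,uniform-by-month convention (4 of 12 months)
age_band,all,7-11,5,,uniform-by-month convention (5 of 12 months)
sex,all,male,6865626,,national vital statistics 2006-2018
sex,all,female,6518337,,national vital statistics 2006-2018
gestational_age,all,<37,762547,,national vital statistics 2006-2018 (4083 unknown excluded)
gestational_age,all,>=37,12617333,,national vital statistics 2006-2018 (4083 unknown excluded)
birth_weight,all,<2500,1276948,,national vital statistics 2006-2018 (2348 unknown excluded)
birth_weight,all,>=2500,12104667,,national vital statistics 2006-2018 (2348 unknown excluded)
co_sleeping,0-2,yes,43,,Ichikawa et al. infant-care survey
co_sleeping,0-2,no,98,,Ichikawa et al. infant-care survey
co_sleeping,3-6,yes,74,,Ichikawa et al. infant-care survey
co_sleeping,3-6,no,65,,Ichikawa et al. infant-care survey
co_sleeping,7-11,yes,85,,Ichikawa et al. infant-care survey
co_sleeping,7-11,no,73,,Ichikawa et al. infant-care survey
sleep_position,all,prone,422,,Togari et al. sleeping-position survey
sleep_position,all,not_prone,1816,,Togari et al. sleeping-position survey
breastfeeding,0-2,yes,3555,,national nutrition survey on preschool children 2015
breastfeeding,0-2,no,148,,national nutrition survey on preschool children 2015
breastfeeding,3-6,yes,4011,,national nutrition survey on preschool children 2015
breastfeeding,3-6,no,700,,national nutrition survey on preschool children 2015
breastfeeding,7-11,yes,,0.811,national nutrition survey 2015 (proportions only)
breastfeeding,7-11,no,,0.189,national nutrition survey 2015 (proportions only)
passive_smoking,all,yes,,0.331,tobacco-consumption prevalence 2018 (proportions only)
passive_smoking,all,no,,0.669,tobacco-consumption prevalence 2018 (proportions only)
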