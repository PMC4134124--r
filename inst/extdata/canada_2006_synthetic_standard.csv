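# Standard population for direct age standardization.
# Synthetic approximation of the 2006 Canadian Census age distribution
# (Statistics Canada, 2006 Census of Population), aggregated to 10-year
# bins and rounded; recorded here so analyses are reproducible offline.
# These counts are a stand-in, not an official census extract; substitute
# any standard via read_standard_population().
# Weights are computed as population / sum(population) at read time.
age_group,population
<10,3500690
10-19,4218155
20-29,4105305
30-39,4291890
40-49,5074285
50-59,4542175
60-69,2989545
70-79,2017475
80+,1373300
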