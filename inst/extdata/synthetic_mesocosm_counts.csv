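year,mesocosm_id,parent_flow_triploid,parent_flow_diploid,dissected_males,dissected_females,offspring_flow_triploid,offspring_flow_diploid,infected_males,infected_females,infected_offspring
2012,M2012_1,40,26,44,106,43,28,3,12,0
2012,M2012_2,22,35,50,100,26,34,3,9,0
2012,M2012_3,31,31,54,96,40,41,6,9,0
2012,M2012_4,32,34,57,93,38,26,4,13,0
2012,M2012_5,19,47,73,77,22,44,10,8,0
2012,M2012_6,36,40,58,92,27,39,5,3,0
2013,M2013_1,19,46,53,97,18,45,3,12,0
2013,M2013_2,21,40,49,101,33,44,3,7,0
2013,M2013_3,16,35,52,98,32,28,7,12,0
2013,M2013_4,24,30,41,109,43,49,4,3,0
2013,M2013_5,8,44,65,85,21,58,4,8,0
2013,M2013_6,30,27,50,100,36,28,7,10,0
2014,M2014_1,20,43,69,81,15,66,4,10,0
2014,M2014_2,19,35,49,101,34,58,6,9,0
2014,M2014_3,15,33,55,95,24,47,5,12,0
2014,M2014_4,45,11,28,122,56,22,1,11,0
2014,M2014_5,53,21,56,94,34,50,6,10,0
2014,M2014_6,29,27,43,107,34,28,3,10,0
2015,M2015_1,39,23,44,106,38,33,1,8,0
2015,M2015_2,15,43,57,93,38,27,4,6,0
2015,M2015_3,18,47,50,100,20,62,5,3,0
2015,M2015_4,30,25,55,95,35,47,6,9,0
2015,M2015_5,21,45,59,91,39,42,6,6,0
2015,M2015_6,38,20,35,115,38,26,7,15,0
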