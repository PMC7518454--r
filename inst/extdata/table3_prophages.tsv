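id	start	end	length	completeness	name
1	1314728	1394436	79.7Kb	Intact	Nef
2	1809906	1835390	25.4Kb	Incomplete	
3	2005260	2015055	9.7Kb	Incomplete	
4	2086138	2130245	44.1Kb	Intact	
5	2182740	2223082	40.3Kb	Intact	
6	2286353	2333386	47.0Kb	Intact	
7	2611252	2651174	39.9Kb	Intact	
8	2849919	2909216	59.2Kb	Intact	KingRac
9	3492665	3543269	50.6Kb	Intact	
10	4655459	4674687	19.2Kb	Incomplete	
11	5206358	5241330	34.9Kb	Questionable	
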