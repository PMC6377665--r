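sample_id	smoking_status	pack_years	family_id
s0001	never	0	s0001
s0002	never	0	s0002
s0003	never	0	s0003
s0004	never	0	s0004
s0005	never	0	s0005
s0006	never	0	s0006
s0007	never	0	s0007
s0008	never	0	s0008
s0009	never	0	s0009
s0010	never	0	s0010
s0011	never	0	s0011
s0012	never	0	s0012
s0013	never	0	s0013
s0014	never	0	s0014
s0015	never	0	s0015
s0016	never	0	s0016
s0017	never	0	s0017
s0018	never	0	s0018
s0019	never	0	s0019
s0020	never	0	s0020
s0021	former	24.9404694511504	s0021
s0022	former	6.22039463441759	s0022
s0023	former	9.74770780430465	s0023
s0024	former	24.6943774021387	s0024
s0025	former	8.74769087742481	s0025
s0026	former	6.92025664050068	s0026
s0027	former	13.938472431546	s0027
s0028	former	17.0135032123438	s0028
s0029	former	6.06771427737398	s0029
s0030	former	10.5138690983984	s0030
s0031	current	10.6405312838314	s0031
s0032	current	3.36529987828384	s0032
s0033	current	11.8747235417325	s0033
s0034	current	26.3431388551719	s0034
s0035	current	19.3722484682516	s0035
s0036	current	5.39610424157615	s0036
s0037	current	14.7538025087978	s0037
s0038	current	9.57058777329932	s0038
s0039	current	10.2949306555933	s0039
s0040	current	19.2559188458013	s0040
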