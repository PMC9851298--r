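# deltarank background network: 220 edges
# orientation = first-seen in source; delta rank sign follows it
gene_a	gene_b
GENE044	GENE017
GENE058	GENE006
GENE012	GENE002
GENE042	GENE053
GENE021	GENE017
GENE055	GENE027
GENE027	GENE045
GENE015	GENE035
GENE046	GENE018
GENE003	GENE016
GENE017	GENE055
GENE016	GENE032
GENE053	GENE049
GENE004	GENE032
GENE004	GENE020
GENE025	GENE042
GENE004	GENE018
GENE059	GENE009
GENE052	GENE030
GENE022	GENE050
GENE053	GENE048
GENE010	GENE053
GENE032	GENE017
GENE060	GENE024
GENE029	GENE006
GENE025	GENE004
GENE052	GENE034
GENE021	GENE025
GENE002	GENE010
GENE047	GENE021
GENE056	GENE017
GENE057	GENE024
GENE038	GENE056
GENE004	GENE017
GENE009	GENE060
GENE048	GENE037
GENE014	GENE045
GENE014	GENE058
GENE035	GENE003
GENE044	GENE039
GENE022	GENE032
GENE041	GENE004
GENE024	GENE002
GENE044	GENE004
GENE028	GENE004
GENE046	GENE050
GENE036	GENE040
GENE056	GENE047
GENE022	GENE011
GENE057	GENE001
GENE031	GENE056
GENE017	GENE010
GENE036	GENE034
GENE001	GENE020
GENE033	GENE003
GENE027	GENE016
GENE048	GENE003
GENE031	GENE037
GENE007	GENE011
GENE003	GENE057
GENE023	GENE024
GENE059	GENE001
GENE003	GENE026
GENE003	GENE049
GENE002	GENE039
GENE049	GENE017
GENE026	GENE056
GENE006	GENE015
GENE042	GENE058
GENE013	GENE035
GENE059	GENE039
GENE046	GENE024
GENE021	GENE020
GENE002	GENE054
GENE037	GENE014
GENE008	GENE019
GENE025	GENE027
GENE006	GENE034
GENE002	GENE059
GENE047	GENE014
GENE020	GENE016
GENE023	GENE056
GENE057	GENE053
GENE031	GENE030
GENE039	GENE043
GENE032	GENE019
GENE057	GENE014
GENE053	GENE031
GENE044	GENE052
GENE056	GENE004
GENE034	GENE051
GENE021	GENE002
GENE043	GENE019
GENE009	GENE041
GENE046	GENE023
GENE059	GENE017
GENE052	GENE056
GENE037	GENE036
GENE014	GENE038
GENE007	GENE015
GENE029	GENE012
GENE014	GENE021
GENE013	GENE028
GENE037	GENE008
GENE058	GENE021
GENE023	GENE052
GENE002	GENE008
GENE031	GENE034
GENE029	GENE004
GENE018	GENE027
GENE030	GENE011
GENE047	GENE057
GENE025	GENE011
GENE003	GENE050
GENE054	GENE001
GENE037	GENE007
GENE034	GENE054
GENE056	GENE003
GENE018	GENE012
GENE002	GENE044
GENE020	GENE057
GENE015	GENE044
GENE058	GENE054
GENE047	GENE018
GENE029	GENE015
GENE043	GENE015
GENE029	GENE005
GENE048	GENE024
GENE016	GENE036
GENE051	GENE050
GENE059	GENE018
GENE024	GENE028
GENE048	GENE013
GENE017	GENE012
GENE038	GENE042
GENE048	GENE060
GENE058	GENE038
GENE051	GENE025
GENE052	GENE027
GENE056	GENE033
GENE048	GENE057
GENE007	GENE006
GENE040	GENE024
GENE040	GENE032
GENE012	GENE058
GENE054	GENE053
GENE006	GENE032
GENE045	GENE005
GENE044	GENE031
GENE030	GENE014
GENE011	GENE016
GENE012	GENE003
GENE042	GENE046
GENE056	GENE022
GENE018	GENE009
GENE053	GENE014
GENE024	GENE053
GENE026	GENE027
GENE034	GENE037
GENE040	GENE043
GENE055	GENE039
GENE017	GENE045
GENE001	GENE014
GENE049	GENE004
GENE059	GENE041
GENE014	GENE054
GENE026	GENE004
GENE059	GENE014
GENE037	GENE057
GENE016	GENE055
GENE039	GENE042
GENE006	GENE059
GENE003	GENE004
GENE054	GENE039
GENE036	GENE058
GENE038	GENE049
GENE036	GENE046
GENE035	GENE006
GENE031	GENE051
GENE001	GENE035
GENE039	GENE052
GENE008	GENE017
GENE025	GENE009
GENE057	GENE018
GENE052	GENE055
GENE057	GENE058
GENE032	GENE041
GENE046	GENE008
GENE050	GENE007
GENE038	GENE035
GENE017	GENE057
GENE059	GENE031
GENE045	GENE011
GENE024	GENE019
GENE014	GENE034
GENE043	GENE001
GENE056	GENE046
GENE009	GENE043
GENE053	GENE035
GENE036	GENE020
GENE050	GENE009
GENE005	GENE012
GENE052	GENE059
GENE016	GENE023
GENE026	GENE025
GENE033	GENE004
GENE007	GENE035
GENE009	GENE020
GENE049	GENE006
GENE054	GENE048
GENE051	GENE037
GENE043	GENE020
GENE053	GENE023
GENE044	GENE003
GENE024	GENE011
GENE036	GENE018
GENE013	GENE047
GENE038	GENE010
GENE034	GENE046
GENE007	GENE020
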