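dsb_id	gene_id	tc	position_class	exon_class
DSB001	GENE001	TRUE	promoter	not_applicable
DSB001	GENE002	TRUE	five_prime	exonic
DSB002	GENE003	TRUE	promoter	not_applicable
DSB002	GENE004	TRUE	five_prime	exonic
DSB003	GENE005	TRUE	promoter	not_applicable
DSB003	GENE006	TRUE	five_prime	exonic
DSB004	GENE007	TRUE	promoter	not_applicable
DSB004	GENE008	TRUE	five_prime	exonic
DSB005	GENE009	TRUE	promoter	not_applicable
DSB005	GENE010	TRUE	five_prime	exonic
DSB006	GENE011	TRUE	promoter	not_applicable
DSB006	GENE012	TRUE	five_prime	exonic
DSB007	GENE013	TRUE	promoter	not_applicable
DSB007	GENE014	TRUE	five_prime	exonic
DSB008	GENE015	TRUE	promoter	not_applicable
DSB008	GENE016	TRUE	five_prime	exonic
DSB009	GENE017	TRUE	promoter	not_applicable
DSB009	GENE018	TRUE	five_prime	exonic
DSB010	GENE019	TRUE	promoter	not_applicable
DSB010	GENE020	TRUE	five_prime	exonic
DSB011	GENE021	TRUE	promoter	not_applicable
DSB011	GENE022	TRUE	five_prime	exonic
DSB012	GENE023	TRUE	promoter	not_applicable
DSB013	GENE024	TRUE	promoter	not_applicable
DSB014	GENE025	TRUE	promoter	not_applicable
DSB015	GENE026	TRUE	promoter	not_applicable
DSB016	GENE027	TRUE	promoter	not_applicable
DSB017	GENE028	TRUE	promoter	not_applicable
DSB018	GENE029	TRUE	promoter	not_applicable
DSB019	GENE030	TRUE	promoter	not_applicable
DSB020	GENE031	TRUE	promoter	not_applicable
DSB021	GENE032	TRUE	promoter	not_applicable
DSB022	GENE033	TRUE	promoter	not_applicable
DSB023	GENE034	TRUE	promoter	not_applicable
DSB024	GENE035	TRUE	promoter	not_applicable
DSB025	GENE036	TRUE	promoter	not_applicable
DSB026	GENE037	TRUE	promoter	not_applicable
DSB027	GENE038	TRUE	promoter	not_applicable
DSB028	GENE039	TRUE	promoter	not_applicable
DSB029	GENE040	TRUE	promoter	not_applicable
DSB030	GENE041	TRUE	promoter	not_applicable
DSB031	GENE042	TRUE	promoter	not_applicable
DSB032	GENE043	TRUE	five_prime	exonic
DSB033	GENE044	TRUE	five_prime	exonic
DSB034	GENE045	TRUE	five_prime	exonic
DSB035	GENE046	TRUE	five_prime	exonic
DSB036	GENE047	TRUE	five_prime	exonic
DSB037	GENE048	TRUE	five_prime	intronic
DSB038	GENE049	TRUE	five_prime	intronic
DSB039	GENE050	TRUE	five_prime	intronic
DSB040	GENE051	TRUE	five_prime	intronic
DSB041	GENE052	TRUE	five_prime	intronic
DSB042	GENE053	TRUE	five_prime	intronic
DSB043	GENE054	TRUE	five_prime	intronic
DSB044	GENE055	TRUE	five_prime	intronic
DSB045	GENE056	TRUE	five_prime	intronic
DSB046	GENE057	TRUE	five_prime	intronic
DSB047	GENE058	TRUE	five_prime	intronic
DSB048	GENE059	TRUE	five_prime	intronic
DSB049	GENE060	TRUE	five_prime	intronic
DSB050	GENE061	TRUE	five_prime	intronic
DSB051	GENE062	TRUE	five_prime	intronic
DSB052	GENE063	TRUE	five_prime	intronic
DSB053	GENE064	TRUE	five_prime	intronic
DSB054	GENE065	TRUE	five_prime	intronic
DSB055	GENE066	TRUE	five_prime	intronic
DSB056	GENE067	TRUE	five_prime	intronic
DSB057	GENE068	TRUE	gene_body	exonic
DSB058	GENE069	TRUE	gene_body	exonic
DSB059	GENE070	TRUE	gene_body	exonic
DSB060	GENE071	TRUE	gene_body	intronic
DSB061	GENE072	TRUE	gene_body	intronic
DSB062	GENE073	TRUE	gene_body	intronic
DSB063	GENE074	TRUE	gene_body	intronic
DSB064	GENE075	TRUE	gene_body	intronic
DSB065	GENE076	TRUE	gene_body	intronic
DSB066	NA	FALSE	intergenic	not_applicable
DSB067	NA	FALSE	intergenic	not_applicable
DSB068	NA	FALSE	intergenic	not_applicable
DSB069	NA	FALSE	intergenic	not_applicable
DSB070	NA	FALSE	intergenic	not_applicable
DSB071	NA	FALSE	intergenic	not_applicable
DSB072	NA	FALSE	intergenic	not_applicable
DSB073	NA	FALSE	intergenic	not_applicable
DSB074	NA	FALSE	intergenic	not_applicable
DSB075	NA	FALSE	intergenic	not_applicable
DSB076	NA	FALSE	intergenic	not_applicable
DSB077	NA	FALSE	intergenic	not_applicable
DSB078	NA	FALSE	intergenic	not_applicable
DSB079	NA	FALSE	intergenic	not_applicable
DSB080	NA	FALSE	intergenic	not_applicable
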