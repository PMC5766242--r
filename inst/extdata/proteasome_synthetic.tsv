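symbol	entrez_id	level1	level2	level3	role	atp
PSMA1	201001	Proteasome	20S_alpha	NA	co-chaperone	not-applicable
PSMA2	201002	Proteasome	20S_alpha	NA	co-chaperone	not-applicable
PSMA3	201003	Proteasome	20S_alpha	NA	co-chaperone	not-applicable
PSMA4	201004	Proteasome	20S_alpha	NA	co-chaperone	not-applicable
PSMA5	201005	Proteasome	20S_alpha	NA	co-chaperone	not-applicable
PSMA6	201006	Proteasome	20S_alpha	NA	co-chaperone	not-applicable
PSMA7	201007	Proteasome	20S_alpha	NA	co-chaperone	not-applicable
PSMB1	201008	Proteasome	20S_beta	NA	co-chaperone	not-applicable
PSMB2	201009	Proteasome	20S_beta	NA	co-chaperone	not-applicable
PSMB3	201010	Proteasome	20S_beta	NA	co-chaperone	not-applicable
PSMB4	201011	Proteasome	20S_beta	NA	co-chaperone	not-applicable
PSMB5	201012	Proteasome	20S_beta	NA	co-chaperone	not-applicable
PSMB6	201013	Proteasome	20S_beta	NA	co-chaperone	not-applicable
PSMB7	201014	Proteasome	20S_beta	NA	co-chaperone	not-applicable
PSMB8	201015	Proteasome	20S_beta	NA	co-chaperone	not-applicable
PSMB9	201016	Proteasome	20S_beta	NA	co-chaperone	not-applicable
PSMB10	201017	Proteasome	20S_beta	NA	co-chaperone	not-applicable
PSMB11	201018	Proteasome	20S_beta	NA	co-chaperone	not-applicable
PSMC1	201019	Proteasome	19S_ATPase	NA	co-chaperone	not-applicable
PSMC2	201020	Proteasome	19S_ATPase	NA	co-chaperone	not-applicable
PSMC3	201021	Proteasome	19S_ATPase	NA	co-chaperone	not-applicable
PSMC4	201022	Proteasome	19S_ATPase	NA	co-chaperone	not-applicable
PSMC5	201023	Proteasome	19S_ATPase	NA	co-chaperone	not-applicable
PSMC6	201024	Proteasome	19S_ATPase	NA	co-chaperone	not-applicable
PSMD1	201025	Proteasome	19S_non_ATPase	NA	co-chaperone	not-applicable
PSMD2	201026	Proteasome	19S_non_ATPase	NA	co-chaperone	not-applicable
PSMD3	201027	Proteasome	19S_non_ATPase	NA	co-chaperone	not-applicable
PSMD4	201028	Proteasome	19S_non_ATPase	NA	co-chaperone	not-applicable
PSMD5	201029	Proteasome	19S_non_ATPase	NA	co-chaperone	not-applicable
PSMD6	201030	Proteasome	19S_non_ATPase	NA	co-chaperone	not-applicable
PSMD7	201031	Proteasome	19S_non_ATPase	NA	co-chaperone	not-applicable
PSMD8	201032	Proteasome	19S_non_ATPase	NA	co-chaperone	not-applicable
PSMD9	201033	Proteasome	19S_non_ATPase	NA	co-chaperone	not-applicable
PSMD10	201034	Proteasome	19S_non_ATPase	NA	co-chaperone	not-applicable
PSMD11	201035	Proteasome	19S_non_ATPase	NA	co-chaperone	not-applicable
PSMD12	201036	Proteasome	19S_non_ATPase	NA	co-chaperone	not-applicable
PSMD13	201037	Proteasome	19S_non_ATPase	NA	co-chaperone	not-applicable
PSMD14	201038	Proteasome	19S_non_ATPase	NA	co-chaperone	not-applicable
PSME1	201039	Proteasome	activator	NA	co-chaperone	not-applicable
PSME2	201040	Proteasome	activator	NA	co-chaperone	not-applicable
PSME3	201041	Proteasome	activator	NA	co-chaperone	not-applicable
PSME4	201042	Proteasome	activator	NA	co-chaperone	not-applicable
PSMF1	201043	Proteasome	inhibitor	NA	co-chaperone	not-applicable
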