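id	aliases	molar_mass	carbon_atoms	role	nadph_gen_per_mol	nadph_req_per_mol	redox_status
glucose	glc	180.16	6	substrate	2	NA	core
glycerol	gly	92.09	3	substrate	2	NA	core
butanol	BuOH|n-butanol	74.12	4	product	NA	4	core
isopropanol	IPA|2-propanol	60.10	3	product	NA	1	core
acetone	ACT	58.08	3	product	NA	0	core
acetic_acid	AA|acetate	60.05	2	product	NA	0	core
butyric_acid	BA|butyrate	88.11	4	product	NA	2	core
pdo_13	1,3-PDO|1,3-propanediol|13pdo	76.09	3	product	NA	1	extrapolated
ethanol	EtOH	46.07	2	product	NA	NA	extrapolated
sucrose		342.30	12	substrate	NA	NA	extrapolated
xylose		150.13	5	substrate	NA	NA	extrapolated
arabinose		150.13	5	substrate	NA	NA	extrapolated
galactose		180.16	6	substrate	NA	NA	extrapolated
mannose		180.16	6	substrate	NA	NA	extrapolated
fructose		180.16	6	substrate	NA	NA	extrapolated
cellobiose		342.30	12	substrate	NA	NA	extrapolated
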