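# Published per-locus group mean counts of circulating 5' tRNA halves
# (young control, old control, old calorie-restricted; three mice per group)
# with the published signed fold changes and likelihood-ratio p-values for
# the age (old vs young control) and CR (old CR vs old control) contrasts.
family	locus	young_control	old_control	old_CR	fc_age_printed	p_age_printed	fc_cr_printed	p_cr_printed
His-GTG	chr4:82619623-82619694	797	2988	1554	3.8	3.1E-11	-2	6.8E-04
His-GTG	chr2:122377363-122377434	798	2994	1549	3.8	3.7E-11	-2	6.4E-04
His-GTG	chr3:96452495-96452566	307	1140	590	3.8	3.8E-11	-2	6.1E-04
His-GTG	chr2:122375494-122375565	808	2990	1533	3.8	3.9E-11	-2	5.0E-04
His-GTG	chr2:122377968-122378039	309	1163	600	3.8	4.2E-11	-2	6.6E-04
His-GTG	chr3:96458070-96458141	802	2993	1523	3.8	4.3E-11	-2	4.8E-04
His-GTG	chr3:96500366-96500437	796	2954	1524	3.8	4.5E-11	-2	5.9E-04
His-GTG	chr3:96410069-96410140	301	1148	590	3.9	2.0E-11	-2	5.5E-04
Arg-CCG	chr11:107012866-107012938	1243	256	302	-5	9.9E-12	1.2	4.7E-01
Cys-GCA	chr11:97798906-97798977	933	370	688	-2.6	2.5E-06	1.8	2.4E-03
Cys-GCA	chr11:97988246-97988317	928	376	700	-2.5	3.9E-06	1.8	2.2E-03
Cys-GCA	chr11:97988923-97988994	930	360	684	-2.6	1.3E-06	1.9	1.5E-03
Gly-GCC	chr1:171074302-171074372	16868	3739	3807	-4.5	3.5E-14	-1	9.6E-01
Gly-GCC	chr1:171066631-171066701	16820	3730	3790	-4.5	4.3E-14	-1	9.6E-01
Gly-GCC	chr1:171081876-171081946	16779	3725	3788	-4.4	5.3E-14	-1	9.6E-01
Lys-CTT	chr17:23533962-23534034	4175	1939	3286	-2.2	8.8E-06	1.7	3.7E-03
Lys-CTT	chr3:96428235-96428307	4215	1964	3353	-2.2	1.0E-05	1.7	3.3E-03
Lys-CTT	chr17:23547360-23547432	4098	1923	3272	-2.2	1.1E-05	1.7	3.4E-03
Lys-CTT	chr17:23535332-23535404	14085	6569	11132	-2.2	1.2E-05	1.7	4.1E-03
Lys-CTT	chr13:23436340-23436412	4181	1962	3321	-2.2	1.2E-05	1.7	3.9E-03
Lys-CTT	chr3:96499512-96499584	13865	6507	11017	-2.2	1.3E-05	1.7	3.9E-03
Lys-CTT	chr11:48833883-48833955	13905	6539	11051	-2.2	1.4E-05	1.7	4.1E-03
Val-AAC	chr13:23401073-23401145	1247	451	814	-2.8	3.3E-07	1.8	4.1E-03
Val-AAC	chr13:23413248-23413320	1246	467	836	-2.7	5.4E-07	1.8	4.0E-03
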