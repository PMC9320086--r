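# Per-region cortical-thickness parameters (mm) used as synthetic-cohort
# defaults: group means and SDs for the two clinical variants and healthy
# controls, Desikan atlas labels, ordered by lobe as in the source study's
# regional table.
lobe	region	hemisphere	mean_svPPA	sd_svPPA	mean_lvPPA	sd_lvPPA	mean_HC	sd_HC
temporal_medial	entorhinal	left	1.77	0.27	2.60	0.51	3.20	0.42
temporal_medial	entorhinal	right	2.28	0.32	2.83	0.47	3.38	0.40
temporal_medial	fusiform	left	1.99	0.25	2.18	0.43	2.56	0.11
temporal_medial	fusiform	right	2.15	0.22	2.30	0.18	2.57	0.11
temporal_medial	parahippocampal	left	1.88	0.24	2.25	0.46	2.58	0.26
temporal_medial	parahippocampal	right	2.01	0.30	2.31	0.38	2.51	0.24
temporal_medial	temporalpole	left	2.34	0.51	3.06	0.59	3.47	0.39
temporal_medial	temporalpole	right	2.83	0.72	3.17	0.53	3.59	0.35
temporal_lateral	bankssts	left	1.87	0.31	1.98	0.24	2.35	0.17
temporal_lateral	bankssts	right	2.06	0.27	2.12	0.23	2.44	0.16
temporal_lateral	inferiortemporal	left	1.99	0.31	2.30	0.37	2.66	0.19
temporal_lateral	inferiortemporal	right	2.36	0.25	2.43	0.23	2.70	0.17
temporal_lateral	middletemporal	left	2.04	0.33	2.34	0.35	2.70	0.18
temporal_lateral	middletemporal	right	2.28	0.23	2.48	0.22	2.72	0.17
temporal_lateral	superiortemporal	left	1.86	0.26	2.17	0.31	2.57	0.17
temporal_lateral	superiortemporal	right	2.16	0.26	2.34	0.21	2.60	0.19
temporal_lateral	transversetemporal	left	1.97	0.37	1.92	0.34	2.21	0.25
temporal_lateral	transversetemporal	right	2.10	0.46	2.16	0.22	2.26	0.25
frontal	caudalmiddlefrontal	left	2.14	0.26	2.05	0.25	2.40	0.16
frontal	caudalmiddlefrontal	right	2.16	0.32	2.18	0.16	2.38	0.12
frontal	frontalpole	left	2.38	0.23	2.56	0.39	2.72	0.25
frontal	frontalpole	right	2.53	0.21	2.70	0.23	2.76	0.29
frontal	lateralorbitofrontal	left	2.27	0.30	2.50	0.34	2.57	0.15
frontal	lateralorbitofrontal	right	2.38	0.19	2.51	0.22	2.52	0.16
frontal	medialorbitofrontal	left	2.12	0.20	2.35	0.36	2.40	0.13
frontal	medialorbitofrontal	right	2.28	0.21	2.45	0.19	2.41	0.19
frontal	paracentral	left	2.05	0.30	1.96	0.32	2.23	0.25
frontal	paracentral	right	2.15	0.19	2.03	0.21	2.23	0.23
frontal	parsopercularis	left	2.22	0.26	2.21	0.24	2.45	0.13
frontal	parsopercularis	right	2.22	0.29	2.29	0.19	2.46	0.12
frontal	parsorbitalis	left	2.34	0.35	2.43	0.32	2.54	0.14
frontal	parsorbitalis	right	2.45	0.18	2.48	0.20	2.52	0.18
frontal	parstriangularis	left	2.13	0.28	2.12	0.27	2.30	0.13
frontal	parstriangularis	right	2.18	0.21	2.25	0.16	2.31	0.10
frontal	precentral	left	2.13	0.30	2.04	0.30	2.38	0.24
frontal	precentral	right	2.20	0.27	2.11	0.26	2.35	0.23
frontal	rostralmiddlefrontal	left	2.01	0.25	2.07	0.24	2.27	0.11
frontal	rostralmiddlefrontal	right	2.09	0.22	2.15	0.13	2.25	0.12
frontal	superiorfrontal	left	2.29	0.31	2.26	0.28	2.54	0.17
frontal	superiorfrontal	right	2.33	0.26	2.35	0.14	2.52	0.14
parietal	inferiorparietal	left	1.93	0.27	1.91	0.28	2.29	0.13
parietal	inferiorparietal	right	2.09	0.20	2.01	0.20	2.32	0.14
parietal	postcentral	left	1.78	0.13	1.72	0.17	2.00	0.15
parietal	postcentral	right	1.81	0.17	1.82	0.13	1.97	0.18
parietal	precuneus	left	1.95	0.24	1.89	0.26	2.23	0.15
parietal	precuneus	right	2.00	0.23	1.99	0.19	2.18	0.17
parietal	superiorparietal	left	1.85	0.22	1.75	0.24	2.08	0.14
parietal	superiorparietal	right	1.92	0.24	1.84	0.16	2.07	0.16
parietal	supramarginal	left	2.13	0.24	1.97	0.22	2.38	0.13
parietal	supramarginal	right	2.21	0.16	2.08	0.12	2.36	0.17
occipital	cuneus	left	1.62	0.15	1.68	0.18	1.81	0.18
occipital	cuneus	right	1.64	0.15	1.66	0.13	1.75	0.20
occipital	lateraloccipital	left	1.94	0.15	1.86	0.21	2.01	0.15
occipital	lateraloccipital	right	1.97	0.20	1.96	0.14	2.09	0.16
occipital	lingual	left	1.80	0.13	1.75	0.22	1.91	0.16
occipital	lingual	right	1.82	0.14	1.81	0.10	1.90	0.16
occipital	pericalcarine	left	1.54	0.17	1.51	0.17	1.55	0.20
occipital	pericalcarine	right	1.50	0.17	1.50	0.18	1.57	0.18
insular	insula	left	2.51	0.29	2.55	0.37	2.91	0.21
insular	insula	right	2.69	0.13	2.68	0.29	2.92	0.20
cingulate	caudalanteriorcingulate	left	2.61	0.19	2.58	0.37	2.68	0.29
cingulate	caudalanteriorcingulate	right	2.53	0.14	2.57	0.28	2.63	0.28
cingulate	isthmuscingulate	left	2.01	0.11	1.97	0.27	2.29	0.24
cingulate	isthmuscingulate	right	2.11	0.13	1.99	0.16	2.26	0.17
cingulate	posteriorcingulate	left	2.09	0.24	2.11	0.34	2.40	0.20
cingulate	posteriorcingulate	right	2.24	0.18	2.19	0.18	2.38	0.19
cingulate	rostralanteriorcingulate	left	2.39	0.32	2.55	0.41	2.80	0.25
cingulate	rostralanteriorcingulate	right	2.62	0.26	2.76	0.25	2.77	0.26
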