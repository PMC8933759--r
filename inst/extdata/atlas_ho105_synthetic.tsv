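roi_id	name	hemisphere	homotopic_partner
L_FP	Left Frontal Pole	L	R_FP
R_FP	Right Frontal Pole	R	L_FP
L_IC	Left Insular Cortex	L	R_IC
R_IC	Right Insular Cortex	R	L_IC
L_SFG	Left Superior Frontal Gyrus	L	R_SFG
R_SFG	Right Superior Frontal Gyrus	R	L_SFG
L_MidFG	Left Middle Frontal Gyrus	L	R_MidFG
R_MidFG	Right Middle Frontal Gyrus	R	L_MidFG
L_IFGtri	Left Inferior Frontal Gyrus, pars triangularis	L	R_IFGtri
R_IFGtri	Right Inferior Frontal Gyrus, pars triangularis	R	L_IFGtri
L_IFGoper	Left Inferior Frontal Gyrus, pars opercularis	L	R_IFGoper
R_IFGoper	Right Inferior Frontal Gyrus, pars opercularis	R	L_IFGoper
L_PreCG	Left Precentral Gyrus	L	R_PreCG
R_PreCG	Right Precentral Gyrus	R	L_PreCG
L_TP	Left Temporal Pole	L	R_TP
R_TP	Right Temporal Pole	R	L_TP
L_aSTG	Left Superior Temporal Gyrus, anterior division	L	R_aSTG
R_aSTG	Right Superior Temporal Gyrus, anterior division	R	L_aSTG
L_pSTG	Left Superior Temporal Gyrus, posterior division	L	R_pSTG
R_pSTG	Right Superior Temporal Gyrus, posterior division	R	L_pSTG
L_aMTG	Left Middle Temporal Gyrus, anterior division	L	R_aMTG
R_aMTG	Right Middle Temporal Gyrus, anterior division	R	L_aMTG
L_pMTG	Left Middle Temporal Gyrus, posterior division	L	R_pMTG
R_pMTG	Right Middle Temporal Gyrus, posterior division	R	L_pMTG
L_toMTG	Left Middle Temporal Gyrus, temporooccipital part	L	R_toMTG
R_toMTG	Right Middle Temporal Gyrus, temporooccipital part	R	L_toMTG
L_aITG	Left Inferior Temporal Gyrus, anterior division	L	R_aITG
R_aITG	Right Inferior Temporal Gyrus, anterior division	R	L_aITG
L_pITG	Left Inferior Temporal Gyrus, posterior division	L	R_pITG
R_pITG	Right Inferior Temporal Gyrus, posterior division	R	L_pITG
L_toITG	Left Inferior Temporal Gyrus, temporooccipital part	L	R_toITG
R_toITG	Right Inferior Temporal Gyrus, temporooccipital part	R	L_toITG
L_PostCG	Left Postcentral Gyrus	L	R_PostCG
R_PostCG	Right Postcentral Gyrus	R	L_PostCG
L_SPL	Left Superior Parietal Lobule	L	R_SPL
R_SPL	Right Superior Parietal Lobule	R	L_SPL
L_aSMG	Left Supramarginal Gyrus, anterior division	L	R_aSMG
R_aSMG	Right Supramarginal Gyrus, anterior division	R	L_aSMG
L_pSMG	Left Supramarginal Gyrus, posterior division	L	R_pSMG
R_pSMG	Right Supramarginal Gyrus, posterior division	R	L_pSMG
L_AG	Left Angular Gyrus	L	R_AG
R_AG	Right Angular Gyrus	R	L_AG
L_sLOC	Left Lateral Occipital Cortex, superior division	L	R_sLOC
R_sLOC	Right Lateral Occipital Cortex, superior division	R	L_sLOC
L_iLOC	Left Lateral Occipital Cortex, inferior division	L	R_iLOC
R_iLOC	Right Lateral Occipital Cortex, inferior division	R	L_iLOC
L_ICC	Left Intracalcarine Cortex	L	R_ICC
R_ICC	Right Intracalcarine Cortex	R	L_ICC
L_SMA	Left Juxtapositional Lobule Cortex	L	R_SMA
R_SMA	Right Juxtapositional Lobule Cortex	R	L_SMA
L_PaCiG	Left Paracingulate Gyrus	L	R_PaCiG
R_PaCiG	Right Paracingulate Gyrus	R	L_PaCiG
L_CC	Left Cuneal Cortex	L	R_CC
R_CC	Right Cuneal Cortex	R	L_CC
L_FOrb	Left Frontal Orbital Cortex	L	R_FOrb
R_FOrb	Right Frontal Orbital Cortex	R	L_FOrb
L_aPaHC	Left Parahippocampal Gyrus, anterior division	L	R_aPaHC
R_aPaHC	Right Parahippocampal Gyrus, anterior division	R	L_aPaHC
L_pPaHC	Left Parahippocampal Gyrus, posterior division	L	R_pPaHC
R_pPaHC	Right Parahippocampal Gyrus, posterior division	R	L_pPaHC
L_LG	Left Lingual Gyrus	L	R_LG
R_LG	Right Lingual Gyrus	R	L_LG
L_aTFusC	Left Temporal Fusiform Cortex, anterior division	L	R_aTFusC
R_aTFusC	Right Temporal Fusiform Cortex, anterior division	R	L_aTFusC
L_pTFusC	Left Temporal Fusiform Cortex, posterior division	L	R_pTFusC
R_pTFusC	Right Temporal Fusiform Cortex, posterior division	R	L_pTFusC
L_TOFusC	Left Temporal Occipital Fusiform Cortex	L	R_TOFusC
R_TOFusC	Right Temporal Occipital Fusiform Cortex	R	L_TOFusC
L_OFusG	Left Occipital Fusiform Gyrus	L	R_OFusG
R_OFusG	Right Occipital Fusiform Gyrus	R	L_OFusG
L_FO	Left Frontal Operculum Cortex	L	R_FO
R_FO	Right Frontal Operculum Cortex	R	L_FO
L_CO	Left Central Opercular Cortex	L	R_CO
R_CO	Right Central Opercular Cortex	R	L_CO
L_PO	Left Parietal Operculum Cortex	L	R_PO
R_PO	Right Parietal Operculum Cortex	R	L_PO
L_PP	Left Planum Polare	L	R_PP
R_PP	Right Planum Polare	R	L_PP
L_HG	Left Heschl's Gyrus	L	R_HG
R_HG	Right Heschl's Gyrus	R	L_HG
L_PT	Left Planum Temporale	L	R_PT
R_PT	Right Planum Temporale	R	L_PT
L_SCC	Left Supracalcarine Cortex	L	R_SCC
R_SCC	Right Supracalcarine Cortex	R	L_SCC
L_OP	Left Occipital Pole	L	R_OP
R_OP	Right Occipital Pole	R	L_OP
MedFC	Frontal Medial Cortex	M	.
SubCalC	Subcallosal Cortex	M	.
AC	Cingulate Gyrus, anterior division	M	.
PC	Cingulate Gyrus, posterior division	M	.
Precuneous	Precuneous Cortex	M	.
L_Thal	Left Thalamus	L	R_Thal
R_Thal	Right Thalamus	R	L_Thal
L_Caud	Left Caudate	L	R_Caud
R_Caud	Right Caudate	R	L_Caud
L_Put	Left Putamen	L	R_Put
R_Put	Right Putamen	R	L_Put
L_Pall	Left Pallidum	L	R_Pall
R_Pall	Right Pallidum	R	L_Pall
L_hippo	Left Hippocampus	L	R_hippo
R_hippo	Right Hippocampus	R	L_hippo
L_amyg	Left Amygdala	L	R_amyg
R_amyg	Right Amygdala	R	L_amyg
L_Accumb	Left Accumbens	L	R_Accumb
R_Accumb	Right Accumbens	R	L_Accumb
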