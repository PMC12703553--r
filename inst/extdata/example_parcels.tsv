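region_id	region_label	hemisphere	network	cluster_overlap
1	l_visual_001	left	visual	visual
2	r_visual_002	right	visual	
3	l_somatomotor_003	left	somatomotor	auditory
4	r_somatomotor_004	right	somatomotor	
5	l_dorsal-attention_005	left	dorsal-attention	manual
6	r_dorsal-attention_006	right	dorsal-attention	
7	l_ventral-attention_007	left	ventral-attention	
8	r_ventral-attention_008	right	ventral-attention	vocal
9	l_limbic_009	left	limbic	
10	r_limbic_010	right	limbic	dual-frontal
11	l_control_011	left	control	
12	r_control_012	right	control	visual
13	l_default_013	left	default	
14	r_default_014	right	default	auditory
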