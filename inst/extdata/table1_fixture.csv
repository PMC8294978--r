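nv_id,patient,age,eye,previous_treatment,initial_injections,retreated,change_structure_post_pct,change_structure_last_pct,change_angio_post_pct,change_angio_last_pct,fd_structure_baseline_pct,fd_structure_post_pct,fd_structure_last_pct,fd_angio_baseline_pct,fd_angio_post_pct,fd_angio_last_pct,last_octa_week,area_structure_baseline,area_structure_post,area_structure_last,area_angio_baseline,area_angio_post,area_angio_last
NV1,A,59,right,none,4,yes,-51,-53,-76,-83,64,38,28,81,69,59,46,1,0.49,0.47,1,0.24,0.17
NV2,A,59,left,none,4,yes,-8,-3,-78,-85,62,25,16,62,66,75,45,1,0.92,0.97,1,0.22,0.15
NV3,B,30,right,PRP_3mo,3,yes_dme,-100,-100,-100,-100,61,0,0,62,0,0,50,1,0,0,1,0,0
NV4,B,30,left,PRP_10mo,3,no,12,-27,-11,13,81,42,40,89,51,53,51,1,1.12,0.73,1,0.89,1.13
NV5,C,48,right,none,3,no,28,196,-65,-20,82,52,49,71,58,54,19,1,1.28,2.96,1,0.35,0.8
NV6,C,48,left,none,3,no,-15,-17,-24,-38,79,26,41,82,36,57,23,1,0.85,0.83,1,0.76,0.62
NV7,D,49,left,none,3,no,16,-6,-32,-34,44,30,41,48,38,45,44,1,1.16,0.94,1,0.68,0.66
NV8,E,51,right,none,3,no,-23,52,-33,-30,76,73,27,79,84,54,48,1,0.77,1.52,1,0.67,0.7
NV9,E,51,right,none,3,no,-27,3,-48,-2,72,65,70,72,83,73,29,1,0.73,1.03,1,0.52,0.98
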