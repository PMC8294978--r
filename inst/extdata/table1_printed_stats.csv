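endpoint,stat,printed,decimals,consistent,note
nv_structure_regression_post,median,15,0,TRUE,
nv_structure_regression_post,range_low,-28,0,TRUE,
nv_structure_regression_post,range_high,100,0,TRUE,
nv_structure_regression_post,mean,18.7,1,TRUE,
nv_structure_regression_post,sd,39.0,1,TRUE,
nv_structure_regression_post,ci_low,-6.8,1,TRUE,
nv_structure_regression_post,ci_high,44.2,1,TRUE,
nv_structure_regression_post,p,0.26,2,TRUE,
nv_structure_regression_last,median,6,0,TRUE,
nv_structure_regression_last,range_low,-196,0,TRUE,
nv_structure_regression_last,range_high,100,0,TRUE,
nv_structure_regression_last,mean,5,0,FALSE,prints mean regression 5; recomputes -5.0 (mean growth); sign/rounding inconsistency
nv_structure_regression_last,sd,82.7,1,TRUE,
nv_structure_regression_last,ci_low,-29.1,1,FALSE,printed CI 49.1 to -29.1 inconsistent with printed SD 82.7; recomputes -59.0
nv_structure_regression_last,ci_high,49.1,1,FALSE,printed CI inconsistent with printed SD; recomputes 49.0
nv_structure_regression_last,p,0.48,2,TRUE,
nv_angio_regression_post,median,48,0,TRUE,
nv_angio_regression_post,range_low,11,0,TRUE,
nv_angio_regression_post,range_high,100,0,TRUE,
nv_angio_regression_post,mean,51.9,1,TRUE,
nv_angio_regression_post,sd,29.5,1,TRUE,
nv_angio_regression_post,ci_low,32.6,1,TRUE,
nv_angio_regression_post,ci_high,71.2,1,TRUE,
nv_angio_regression_post,p,0.007,3,FALSE,prints 0.007; recomputes 0.0077 (truncated rather than rounded)
nv_angio_regression_last,median,34,0,TRUE,
nv_angio_regression_last,range_low,-13,0,TRUE,
nv_angio_regression_last,range_high,100,0,TRUE,
nv_angio_regression_last,mean,42.1,1,TRUE,
nv_angio_regression_last,sd,39.1,1,TRUE,
nv_angio_regression_last,ci_low,16.6,1,TRUE,
nv_angio_regression_last,ci_high,67.7,1,TRUE,
nv_angio_regression_last,p,0.015,3,TRUE,
fd_structure_baseline,median,72,0,TRUE,
fd_structure_baseline,range_low,44,0,TRUE,
fd_structure_baseline,range_high,82,0,TRUE,
fd_structure_post,median,38,0,TRUE,
fd_structure_post,range_low,0,0,TRUE,
fd_structure_post,range_high,73,0,TRUE,
fd_structure_last,median,40,0,TRUE,
fd_structure_last,range_low,0,0,TRUE,
fd_structure_last,range_high,70,0,TRUE,
fd_angio_baseline,median,72,0,TRUE,
fd_angio_baseline,range_low,48,0,TRUE,
fd_angio_baseline,range_high,89,0,TRUE,
fd_angio_post,median,58,0,TRUE,
fd_angio_post,range_low,0,0,TRUE,
fd_angio_post,range_high,84,0,TRUE,
fd_angio_last,median,54,0,TRUE,
fd_angio_last,range_low,0,0,TRUE,
fd_angio_last,range_high,75,0,TRUE,
fd_structure_decrease_post,mean,33,0,FALSE,prints 33; recomputes 30.0 from the published integers (likely computed from unrounded source data)
fd_structure_decrease_post,sd,19.2,1,FALSE,prints 19.2; recomputes 19.8
fd_structure_decrease_post,ci_low,20.5,1,FALSE,derived from the inconsistent mean/SD; recomputes 17.0
fd_structure_decrease_post,ci_high,45.5,1,FALSE,derived from the inconsistent mean/SD; recomputes 43.0
fd_structure_decrease_post,p,0.0077,4,TRUE,
fd_structure_decrease_last,mean,34.3,1,TRUE,
fd_structure_decrease_last,sd,19.8,1,TRUE,
fd_structure_decrease_last,ci_low,21.4,1,TRUE,
fd_structure_decrease_last,ci_high,47.3,1,TRUE,
fd_structure_decrease_last,p,0.0077,4,TRUE,
fd_angio_decrease_post,mean,17.9,1,TRUE,
fd_angio_decrease_post,sd,25.2,1,TRUE,
fd_angio_decrease_post,ci_low,1.4,1,TRUE,
fd_angio_decrease_post,ci_high,34.4,1,TRUE,
fd_angio_decrease_post,p,0.066,3,TRUE,
fd_angio_decrease_last,mean,19.7,1,FALSE,prints 19.7; recomputes 19.6
fd_angio_decrease_last,sd,22.0,1,FALSE,prints 22.0; recomputes 22.1
fd_angio_decrease_last,ci_low,5.31,2,FALSE,derived from the inconsistent mean/SD; recomputes 5.13
fd_angio_decrease_last,ci_high,34.0,1,FALSE,derived from the inconsistent mean/SD; recomputes 34.0
fd_angio_decrease_last,p,0.025,3,FALSE,prints 0.025; recomputes 0.028 under the identified variant
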