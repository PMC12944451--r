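# Default pediatric vancomycin population prior.
#
# Typical-value structure follows the one-compartment pediatric vancomycin
# population model of Le et al. (2014): allometric weight on clearance with
# serum-creatinine and age covariates, volume proportional to weight.
# Covariate symbols available in the expressions: age_mo, age_days, wt (kg),
# scr (mg/dL).
#
# FLAGGED ASSUMPTIONS: the between-subject variances (omega2), the residual
# error magnitude (sigma) and the between-occasion variance (iov2) below are
# representative pediatric values chosen for this package, NOT estimates
# transcribed from that analysis. Replace them if you have a fitted model.
name: le2014_pediatric
cl_expr: 0.248 * wt^0.75 * (0.48/scr)^0.361 * (log(age_days)/7.8)^0.995
v_expr: 0.636 * wt
omega2:
  cl: 0.09
  v: 0.04
sigma:
  prop_cv: 0.2
  add_sd: 0.0
iov2: 0.02
penalty_space: eta
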