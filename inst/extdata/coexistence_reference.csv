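kind,valence,eps_cc,eps_nt,dilute_density,dense_density,n_corelets,source
CORELET,6,3.5,0,1.71e-05,5.76e-05,48,desk-scale dispersed-start coexistence run (120 tau_d; seed 21); see scripts/calibrate.R
ENDOGENOUS,NA,3.5,0,8.0e-05,4.0e-04,128,desk-scale estimate (synthetic placeholder pending endogenous calibration); see scripts/calibrate.R
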