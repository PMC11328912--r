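system,freq_calc_cm1,freq_exp_cm1,tau_calc_ps,tau_calc_err_ps,tau_exp_ps,tau_exp_err_ps,delta_calc_cm1,delta_calc_err_cm1,delta_exp_cm1,delta_exp_ir_cm1,exclude_freq_fit,exclude_delta_fit
D2O,1680,1623,0.82,0.03,1.2,,20.9,0.3,19.75,8.2,FALSE,TRUE
CLF,1712,1669,1.6,0.7,1.9,0.1,12.1,0.3,13.57,7.7,FALSE,FALSE
DMSO,1712,1668,1.3,0.2,1.7,0.1,10.95,0.08,11.55,6.1,FALSE,FALSE
THF,1727,1684,1.02,0.06,1.5,0.1,9.1,0.1,,3.1,FALSE,FALSE
TOL,1747,1686,1.06,0.07,1.6,0.2,7.0,0.2,,3.4,TRUE,FALSE
DMSO_THF,1721,1676,1.9,0.1,2.0,0.2,10.2,0.1,,6.1,FALSE,FALSE
DMSO_D2O,1696,1646,3.8,0.2,3.1,0.3,14.6,0.2,,11.1,FALSE,FALSE
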