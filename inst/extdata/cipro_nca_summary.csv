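parameter,brand,mean,sd,starred
tmax,A,1,0,FALSE
tmax,B,1,0,FALSE
tmax,C,1.5,0,FALSE
tmax,D,1,0,FALSE
tmax,E,1,0,FALSE
tmax,F,1,0,FALSE
cmax,A,11,0.12,FALSE
cmax,B,10.83,0.13,FALSE
cmax,C,9.73,0.16,FALSE
cmax,D,11.64,0.11,FALSE
cmax,E,10.87,0.11,FALSE
cmax,F,10.35,0.13,FALSE
auc_last,A,47.99,0.35,FALSE
auc_last,B,40.04,0.52,TRUE
auc_last,C,44.23,0.72,FALSE
auc_last,D,44.44,0.62,FALSE
auc_last,E,47.97,0.22,FALSE
auc_last,F,45.763,0.49,FALSE
lambda_z,A,0.23,0.01,FALSE
lambda_z,B,0.23,0.008,FALSE
lambda_z,C,0.23,0.015,FALSE
lambda_z,D,0.23,0.01,FALSE
lambda_z,E,0.21,0.01,FALSE
lambda_z,F,0.177,0.01,FALSE
hl_lambda_z,A,3.001,0.19,FALSE
hl_lambda_z,B,2.99,0.19,FALSE
hl_lambda_z,C,3.02,0.195,FALSE
hl_lambda_z,D,3.00,0.18,FALSE
hl_lambda_z,E,3.33,0.17,FALSE
hl_lambda_z,F,4.17,0.20,FALSE
auc_inf,A,57.45,2.07,FALSE
auc_inf,B,47.42,1.95,TRUE
auc_inf,C,53.46,2.10,FALSE
auc_inf,D,52.89,1.54,FALSE
auc_inf,E,59.58,1.14,FALSE
auc_inf,F,62.24,1.98,FALSE
vz_f,A,37.67,1.02,FALSE
vz_f,B,45.51,0.95,FALSE
vz_f,C,40.76,1.072,FALSE
vz_f,D,40.96,1.24,FALSE
vz_f,E,40.31,1.34,FALSE
vz_f,F,48.32,0.89,FALSE
cl_f,A,8.703,0.21,FALSE
cl_f,B,10.54,0.25,FALSE
cl_f,C,9.36,0.37,FALSE
cl_f,D,9.45,0.24,FALSE
cl_f,E,8.39,0.16,FALSE
cl_f,F,8.04,0.26,FALSE
aumc_last,A,138.02,3.12,FALSE
aumc_last,B,109.93,3.29,TRUE
aumc_last,C,130.55,4.62,FALSE
aumc_last,D,124.23,3.65,FALSE
aumc_last,E,140.69,1.36,FALSE
aumc_last,F,140.03,3.25,FALSE
mrt_last,A,2.87,0.04,FALSE
mrt_last,B,2.74,0.03,FALSE
mrt_last,C,2.95,0.06,FALSE
mrt_last,D,2.79,0.04,FALSE
mrt_last,E,2.93,0.03,FALSE
mrt_last,F,3.06,0.04,FALSE
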