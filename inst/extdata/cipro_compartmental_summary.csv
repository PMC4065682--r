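parameter,brand,mean,sd,starred
A,A,12.56,0.12,FALSE
A,B,17.73,0.17,FALSE
A,C,1.24,0.09,FALSE
A,D,1.05,0.13,FALSE
A,E,1.20,0.11,FALSE
A,F,22.46,0.21,FALSE
B,A,11.36,0.05,FALSE
B,B,10.44,0.12,FALSE
B,C,11.82,0.08,FALSE
B,D,12.44,0.24,FALSE
B,E,11.59,0.07,FALSE
B,F,9.94,0.19,TRUE
alpha,A,2.01,0.04,FALSE
alpha,B,2.03,0.05,FALSE
alpha,C,0.64,0.15,FALSE
alpha,D,0.24,0.12,FALSE
alpha,E,0.25,0.06,FALSE
alpha,F,2.22,0.05,FALSE
beta,A,0.24,0.005,FALSE
beta,B,0.23,0.007,FALSE
beta,C,0.22,0.003,FALSE
beta,D,0.23,0.004,FALSE
beta,E,0.21,0.006,FALSE
beta,F,0.16,0.002,TRUE
k12,A,0.57,0.02,FALSE
k12,B,0.62,0.03,FALSE
k12,C,0.01,0.006,FALSE
k12,D,0.07,0.003,FALSE
k12,E,0.01,0.007,FALSE
k12,F,0.77,0.102,FALSE
k21,A,1.16,0.24,FALSE
k21,B,1.28,0.32,FALSE
k21,C,0.63,0.13,FALSE
k21,D,0.01,0.003,FALSE
k21,E,0.24,0.093,FALSE
k21,F,1.35,0.052,FALSE
auc_model,A,56.20,1.85,FALSE
auc_model,B,46.60,2.54,TRUE
auc_model,C,52.92,2.48,FALSE
auc_model,D,74.53,3.57,FALSE
auc_model,E,61.15,4.25,FALSE
auc_model,F,62.23,3.27,FALSE
alpha_hl,A,0.37,0.01,FALSE
alpha_hl,B,0.34,0.05,FALSE
alpha_hl,C,1.84,0.03,FALSE
alpha_hl,D,1.56,0.06,FALSE
alpha_hl,E,3.63,0.02,FALSE
alpha_hl,F,0.31,0.04,FALSE
beta_hl,A,3.01,0.25,FALSE
beta_hl,B,3.07,0.37,FALSE
beta_hl,C,3.15,0.29,FALSE
beta_hl,D,2.99,0.21,FALSE
beta_hl,E,3.43,0.035,FALSE
beta_hl,F,4.32,0.33,TRUE
v1_f,A,29.20,2.54,FALSE
v1_f,B,29.90,2.96,FALSE
v1_f,C,41.73,3.51,FALSE
v1_f,D,41.80,3.21,FALSE
v1_f,E,40.62,3.24,FALSE
v1_f,F,30.41,3.75,FALSE
cl_f,A,10.90,0.34,FALSE
cl_f,B,10.70,0.42,FALSE
cl_f,C,9.46,0.63,FALSE
cl_f,D,6.70,0.41,FALSE
cl_f,E,8.19,0.95,FALSE
cl_f,F,8.04,0.85,FALSE
v2_f,A,11.36,0.23,FALSE
v2_f,B,14.50,0.39,FALSE
v2_f,C,0.23,0.03,FALSE
v2_f,D,10.35,0.51,FALSE
v2_f,E,1.30,0.24,FALSE
v2_f,F,17.33,1.61,FALSE
tmax,A,0.54,0.1,FALSE
tmax,B,0.60,0.3,FALSE
tmax,C,0.99,0.3,FALSE
tmax,D,0.56,0.2,FALSE
tmax,E,0.61,0.09,FALSE
tmax,F,0.60,0.07,FALSE
cmax,A,10.89,0.95,FALSE
cmax,B,10.57,1.73,FALSE
cmax,C,9.57,0.93,FALSE
cmax,D,10.49,1.01,FALSE
cmax,E,10.84,0.57,FALSE
cmax,F,10.45,0.85,FALSE
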