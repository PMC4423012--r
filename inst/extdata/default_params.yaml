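ERSS_T: 1.0
AUT_T: 1.0
APO_T: 1.0
ka_e: 0.009
ki_e: 0.171
kaau: 0.096
kaau_p: 0.45
J_aa: 0.043
J_ia: 0.02
kiau: 0.1
kiau_p: 1.5
kaap: 0.414
kiap: 1.32
kiap_p: 0.177
n_steps: 3
k_fb: 3000.0
sigma_S: 0.26
Omega: 100
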