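# Niederer-Hunter-Smith 2006 active-tension model, original (rat/guinea-pig)
# parameter set. Human-tissue simulations apply human_adjustments() on top.
# name value unit
k_on          100       1/(mM*ms)
k_ref_off     0.2       1/ms
gamma_trpn    2.0       1
ca_trpn_max   0.07      mM
alpha_0       0.008     1/ms
alpha_r1      0.002     1/ms
alpha_r2      0.00175   1/ms
n_rel         3.0       1
K_z           0.15      1
n_hill        3.0       1
ca_50ref      0.00105   mM
z_p           0.85      1
beta_0        4.9       1
beta_1        -4.0      1
T_ref         56.2      kPa
a_xb          0.35      1
A1            -29.0     1
A2            138.0     1
A3            129.0     1
alpha_1       0.03      1/ms
alpha_2       0.13      1/ms
alpha_3       0.625     1/ms
lambda_lo     0.8       1
lambda_hi     1.15      1
k_off_min_frac 0.1      1
dlam_tau      2.0       ms
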