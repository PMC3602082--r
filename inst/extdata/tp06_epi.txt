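# TP06 human epicardial ventricular myocyte parameters
# (ten Tusscher & Panfilov 2006 reference parameter list, epicardial variant)
# name value unit
R_gas      8314.472    mJ/(mol*K)
T_temp     310         K
F_faraday  96485.3415  C/mol
Cm         0.185       uF
V_c        0.016404    nL
V_sr       0.001094    nL
V_ss       0.00005468  nL
K_o        5.4         mM
Na_o       140.0       mM
Ca_o       2.0         mM
G_Na       14.838      nS/pF
G_K1       5.405       nS/pF
G_to       0.294       nS/pF
G_Kr       0.153       nS/pF
G_Ks       0.392       nS/pF
G_CaL      0.0000398   L/(F*ms)
G_bNa      0.00029     nS/pF
G_bCa      0.000592    nS/pF
G_pCa      0.1238      pA/pF
K_pCa      0.0005      mM
G_pK       0.0146      nS/pF
p_KNa      0.03        1
P_NaK      2.724       pA/pF
K_mK       1.0         mM
K_mNa      40.0        mM
k_NaCa     1000        pA/pF
K_mNai     87.5        mM
K_mCa      1.38        mM
k_sat      0.1         1
gamma_NaCa 0.35        1
alpha_NaCa 2.5         1
Vmax_up    0.006375    mM/ms
K_up       0.00025     mM
V_rel      0.102       1/ms
k1_prime   0.15        1/(mM^2*ms)
k2_prime   0.045       1/(mM*ms)
k3         0.060       1/ms
k4         0.005       1/ms
EC         1.5         mM
max_sr     2.5         1
min_sr     1.0         1
V_leak     0.00036     1/ms
V_xfer     0.0038      1/ms
Buf_c      0.2         mM
K_bufc     0.001       mM
Buf_sr     10.0        mM
K_bufsr    0.3         mM
Buf_ss     0.4         mM
K_bufss    0.00025     mM
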