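state_label: OVX_E2
values:
  g_NaT: 260.0
  g_NaP: 0.99690000000000001
  g_A: 23.60000000000000142
  g_BK: 20.0
  g_h: 4.00199999999999978
  g_SK: 28.10000000000000142
  g_M: 2.54000000000000004
  g_T: 5.0
  g_Ca: 2.79999999999999982
  g_TRPC5: 6.59999999999999964
  g_GIRK: 1.19999999999999996
  g_leak: 1.0
  E_Na: 60.0
  E_K: -90.0
  E_Ca: 60.0
  E_h: -30.0
  E_TRPC5: 0.0
  E_leak: -76.79999999999999716
  C_m: 19.0
  Ca_rest: 0.05
  tau_Ca: 336.60000000000002274
  alpha_Ca: 2.37670825906120004e-05
  f_TRPC5: 0.10000000000000001
  K_SK: 0.29999999999999999
  n_SK: 4.0
  K_TRPC5_Ca: 0.25
  n_TRPC5: 3.0
  c_base: 0.29770000000000002
  bk_ca_shift: -20.0
  girk_v_half: -50.0
  girk_k: 15.0
  tau_NKB_rise: 200.0
  tau_NKB_decay: 1000.0
  tau_Dyn_rise: 200.0
  tau_Dyn_decay: 1000.0
  mNaT_vh: -45.0
  mNaT_k: 6.0
  mNaT_exp: 3.0
  mNaT_floor: 0.0
  mNaT_tau_min: 0.05
  mNaT_tau_amp: 0.10000000000000001
  mNaT_tau_vh: -30.0
  mNaT_tau_k: 10.0
  hNaT_vh: -54.0
  hNaT_k: -4.5
  hNaT_exp: 1.0
  hNaT_floor: 0.0
  hNaT_tau_min: 0.29999999999999999
  hNaT_tau_amp: 3.86399999999999988
  hNaT_tau_vh: -55.0
  hNaT_tau_k: 15.0
  pNaP_vh: -50.0
  pNaP_k: 6.0
  pNaP_exp: 1.0
  pNaP_floor: 0.0
  pNaP_tau_min: 5.0
  pNaP_tau_amp: 0.0
  pNaP_tau_vh: -50.0
  pNaP_tau_k: 15.0
  mA_vh: -20.0
  mA_k: 10.0
  mA_exp: 1.0
  mA_floor: 0.0
  mA_tau_min: 1.5
  mA_tau_amp: 2.57299999999999995
  mA_tau_vh: -45.0
  mA_tau_k: 10.0
  hA_vh: -60.0
  hA_k: -8.0
  hA_exp: 1.0
  hA_floor: 0.14999999999999999
  hA_tau_min: 30.0
  hA_tau_amp: 50.0
  hA_tau_vh: -60.0
  hA_tau_k: 20.0
  bBK_vh: 46.14999999999999858
  bBK_k: 12.0
  bBK_exp: 1.0
  bBK_floor: 0.0
  bBK_tau_min: 1.0
  bBK_tau_amp: 2.0
  bBK_tau_vh: 0.0
  bBK_tau_k: 20.0
  rh_vh: -70.0
  rh_k: -8.0
  rh_exp: 1.0
  rh_floor: 0.0
  rh_tau_min: 50.0
  rh_tau_amp: 150.0
  rh_tau_vh: -85.0
  rh_tau_k: 15.0
  wM_vh: -45.0
  wM_k: 6.0
  wM_exp: 1.0
  wM_floor: 0.0
  wM_tau_min: 108.90000000000000568
  wM_tau_amp: 100.0
  wM_tau_vh: -50.0
  wM_tau_k: 20.0
  mT_vh: -50.5
  mT_k: 5.0
  mT_exp: 1.0
  mT_floor: 0.0
  mT_tau_min: 2.0
  mT_tau_amp: 4.0
  mT_tau_vh: -50.0
  mT_tau_k: 15.0
  hT_vh: -75.5
  hT_k: -5.0
  hT_exp: 1.0
  hT_floor: 0.0
  hT_tau_min: 8.0
  hT_tau_amp: 73.90000000000000568
  hT_tau_vh: -75.0
  hT_tau_k: 10.0
  mCa_vh: -32.29999999999999716
  mCa_k: 7.0
  mCa_exp: 1.0
  mCa_floor: 0.0
  mCa_tau_min: 1.0
  mCa_tau_amp: 6.0
  mCa_tau_vh: -30.0
  mCa_tau_k: 15.0
  hCa_vh: -48.89999999999999858
  hCa_k: -6.20000000000000018
  hCa_exp: 1.0
  hCa_floor: 0.25
  hCa_tau_min: 300.0
  hCa_tau_amp: 0.0
  hCa_tau_vh: -50.0
  hCa_tau_k: 15.0
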