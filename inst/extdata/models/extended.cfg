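$amp_IFNg = 2;
$amp_IL2 = 2;
$clonal_exp_rate = 0.05;
$d_Antigen = 0.0416666666666667;
$d_ANXA1 = 0.0416666666666667;
$d_ATP = 5;
$d_CALR = 0.0416666666666667;
$d_ChemoT = 0.00962704417444368;
$d_CTL = 0.00416666666666667;
$d_CXCL10 = 5;
$d_HMGB1 = 0.0416666666666667;
$d_IFN1 = 5;
$d_IFNg = 5;
$d_IL12 = 5;
$d_IL1B = 5;
$d_IL2 = 5;
$d_IL4 = 5;
$d_IL6 = 5;
$d_TGFb = 5;
$d_TNFa = 5;
$direct_cyt = 0.00002;
$Initcd4 = 0.05;
$Initcd8 = 0.05;
$InitDC = 0.1;
$InitTumor = 0.8;
$k_CD28 = 0;
$k_CXCR3 = 0;
$k_FPR1 = 0;
$k_IFN1_rec = 0;
$k_IFNg_rec = 0;
$k_IL12_rec = 0;
$k_IL1B_rec = 0;
$k_IL2_rec = 0;
$k_IL4_rec = 0;
$k_IL6_rec = 0;
$k_kill = 0;
$k_LRP1 = 0;
$k_P2X7R = 0;
$k_P2Y2R = 0;
$k_perf_loss = 0;
$k_TCR_I = 0;
$k_TCR_II = 0;
$k_TGFb_rec = 0;
$k_TLR4 = 0;
$k_TNFa_rec = 0;
$kill_full = 1;
$perf_loss_full = 0.166666666666667;
$s_CD28 = 0.2;
$s_CXCR3 = 2;
$s_FPR1 = 1;
$s_IFN1_rec = 2;
$s_IFNg_rec = 2;
$s_IL12_rec = 10;
$s_IL1B_rec = 10;
$s_IL2_rec = 2;
$s_IL4_rec = 10;
$s_IL6_rec = 10;
$s_LRP1 = 0.05;
$s_P2X7R = 1;
$s_P2Y2R = 1;
$s_TCR_I = 1;
$s_TCR_II = 1;
$s_TGFb_rec = 10;
$s_TLR4 = 1;
$s_TNFa_rec = 1;
$u_aDC = 5;
$u_AgUptake = 0.166666666666667;
$u_Antigen = 0.166666666666667;
$u_ANXA1 = 0.166666666666667;
$u_ATP = 0.25;
$u_CALR = 0.25;
$u_CCR7 = 0.166666666666667;
$u_cd4_Act = 5;
$u_CD40 = 0.166666666666667;
$u_CD80 = 0.166666666666667;
$u_CD86 = 0.166666666666667;
$u_CTL = 0.416666666666667;
$u_CXCL10 = 0.166666666666667;
$u_DyingTumorCell = 1;
$u_HMGB1 = 0.166666666666667;
$u_IFN1 = 0.166666666666667;
$u_IFNg = 0.166666666666667;
$u_IL12 = 0.166666666666667;
$u_IL1B = 0.166666666666667;
$u_IL2 = 0.166666666666667;
$u_IL4 = 0.166666666666667;
$u_IL6 = 0.166666666666667;
$u_MHC_I = 0.166666666666667;
$u_MHC_II = 0.166666666666667;
$u_Perforin = 0.166666666666667;
$u_preCTL = 5;
$u_TGFb = 0.166666666666667;
$u_Th1 = 5;
$u_Th17 = 5;
$u_Th2 = 5;
$u_TNFa = 0.166666666666667;
$u_Treg = 5;
$u_TumorDiv = 0.00001;
init 0.8 : ChemoT = 1, TumorCell = 1;
init 0.1 : DC = 1;
init 0.05 : cd4 = 1;
init 0.05 : cd8 = 1;
set horizon = 300;
set time_step = 2;
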