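death Death;
division Division;
update $k_CD28 = $s_CD28 * p(CD80);
update $k_CXCR3 = $s_CXCR3 * p(CXCL10_o);
update $k_FPR1 = $s_FPR1 * p(ANXA1);
update $k_IFN1_rec = $s_IFN1_rec * p(IFN1_o);
update $k_IFNg_rec = $s_IFNg_rec * p(IFNg_o);
update $k_IL12_rec = $s_IL12_rec * p(IL12_o);
update $k_IL1B_rec = $s_IL1B_rec * p(IL1B_o);
update $k_IL2_rec = $s_IL2_rec * p(IL2_o);
update $k_IL4_rec = $s_IL4_rec * p(IL4_o);
update $k_IL6_rec = $s_IL6_rec * p(IL6_o);
update $k_kill = $kill_full * p(CTL & Perforin);
update $k_LRP1 = $s_LRP1 * p(CALR);
update $k_P2X7R = $s_P2X7R * p(ATP);
update $k_P2Y2R = $s_P2Y2R * p(ATP);
update $k_perf_loss = $perf_loss_full * p(TumorCell);
update $k_TCR_I = $s_TCR_I * p(MHC_I);
update $k_TCR_II = $s_TCR_II * p(MHC_II);
update $k_TGFb_rec = $s_TGFb_rec * p(TGFb_o);
update $k_TLR4 = $s_TLR4 * p(HMGB1);
update $k_TNFa_rec = $s_TNFa_rec * p(TNFa_o);
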