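node aDC {
  rate_up = DC & P2X7R ? $u_aDC : 0;
  rate_down = 0;
}

node AgUptake {
  rate_up = aDC & LRP1 ? $u_AgUptake : 0;
  rate_down = 0;
}

node Antigen {
  rate_up = DyingTumorCell ? $u_Antigen : 0;
  rate_down = $d_Antigen;
}

node ANXA1 {
  rate_up = DyingTumorCell ? $u_ANXA1 : 0;
  rate_down = $d_ANXA1;
}

node ATP {
  rate_up = DyingTumorCell ? $u_ATP : 0;
  rate_down = $d_ATP;
}

node CALR {
  rate_up = DyingTumorCell ? $u_CALR : 0;
  rate_down = $d_CALR;
}

node CCR7 {
  rate_up = aDC ? $u_CCR7 : 0;
  rate_down = 0;
}

node CD28 {
  rate_up = (cd4 | cd8) & CXCR3 ? $k_CD28 : 0;
  rate_down = 0;
}

node cd4 {
  rate_up = 0;
  rate_down = 0;
}

node cd4_Act {
  rate_up = cd4 & TCR_II & CD28 ? $u_cd4_Act : 0;
  rate_down = 0;
}

node CD40 {
  rate_up = aDC & AgUptake & CCR7 ? $u_CD40 : 0;
  rate_down = 0;
}

node cd8 {
  rate_up = 0;
  rate_down = 0;
}

node CD80 {
  rate_up = aDC & AgUptake & CCR7 ? $u_CD80 : 0;
  rate_down = 0;
}

node CD86 {
  rate_up = aDC & AgUptake & CCR7 ? $u_CD86 : 0;
  rate_down = 0;
}

node ChemoT {
  rate_up = 0;
  rate_down = $d_ChemoT;
}

node CTL {
  rate_up = preCTL & TCR_I & (IFNg_rec | IL2_rec) ? $u_CTL : 0;
  rate_down = 0;
}

node CXCL10_o {
  rate_up = (TumorCell | aDC) & IFN1_rec ? $u_CXCL10 : 0;
  rate_down = $d_CXCL10;
}

node CXCR3 {
  rate_up = cd4 | cd8 ? $k_CXCR3 : 0;
  rate_down = 0;
}

node DC {
  rate_up = 0;
  rate_down = 0;
}

node Death {
  rate_up = TumorCell ? $k_kill + (DyingTumorCell ? $direct_cyt : 0) : CTL ? $d_CTL : 0;
  rate_down = 0;
}

node Division {
  rate_up = TumorCell & !DyingTumorCell ? $u_TumorDiv : cd4_Act | Th1 | Th2 | Th17 | Treg | preCTL | CTL ? $clonal_exp_rate : 0;
  rate_down = 0;
}

node DyingTumorCell {
  rate_up = TumorCell & ChemoT ? $u_DyingTumorCell : 0;
  rate_down = 0;
}

node FPR1 {
  rate_up = DC ? $k_FPR1 : 0;
  rate_down = 0;
}

node HMGB1 {
  rate_up = DyingTumorCell & ANXA1 ? $u_HMGB1 : 0;
  rate_down = $d_HMGB1;
}

node IFN1_o {
  rate_up = DyingTumorCell ? $u_IFN1 : 0;
  rate_down = $d_IFN1;
}

node IFN1_rec {
  rate_up = TumorCell | DC ? $k_IFN1_rec : 0;
  rate_down = 0;
}

node IFNg_o {
  rate_up = cd4_Act | Th1 | CTL ? $u_IFNg * (IL12_rec ? $amp_IFNg : 1) : 0;
  rate_down = $d_IFNg;
}

node IFNg_rec {
  rate_up = preCTL ? $k_IFNg_rec : 0;
  rate_down = 0;
}

node IL12_o {
  rate_up = aDC ? $u_IL12 : 0;
  rate_down = $d_IL12;
}

node IL12_rec {
  rate_up = cd4_Act ? $k_IL12_rec : 0;
  rate_down = 0;
}

node IL1B_o {
  rate_up = aDC ? $u_IL1B : 0;
  rate_down = $d_IL1B;
}

node IL1B_rec {
  rate_up = cd4_Act ? $k_IL1B_rec : 0;
  rate_down = 0;
}

node IL2_o {
  rate_up = aDC | cd4_Act | Th1 | Th2 ? $u_IL2 * ((cd4_Act | Th1 | Th2) & CD28 ? $amp_IL2 : 1) : 0;
  rate_down = $d_IL2;
}

node IL2_rec {
  rate_up = cd4_Act | preCTL ? $k_IL2_rec : 0;
  rate_down = 0;
}

node IL4_o {
  rate_up = cd4_Act | Th2 | preCTL ? $u_IL4 : 0;
  rate_down = $d_IL4;
}

node IL4_rec {
  rate_up = cd4_Act ? $k_IL4_rec : 0;
  rate_down = 0;
}

node IL6_o {
  rate_up = aDC ? $u_IL6 : 0;
  rate_down = $d_IL6;
}

node IL6_rec {
  rate_up = cd4_Act ? $k_IL6_rec : 0;
  rate_down = 0;
}

node LRP1 {
  rate_up = DC ? $k_LRP1 : 0;
  rate_down = 0;
}

node MHC_I {
  rate_up = aDC & AgUptake & CCR7 ? $u_MHC_I : 0;
  rate_down = 0;
}

node MHC_II {
  rate_up = aDC & AgUptake & CCR7 ? $u_MHC_II : 0;
  rate_down = 0;
}

node P2X7R {
  rate_up = DC ? $k_P2X7R : 0;
  rate_down = 0;
}

node P2Y2R {
  rate_up = DC ? $k_P2Y2R : 0;
  rate_down = 0;
}

node Perforin {
  rate_up = CTL ? $u_Perforin : 0;
  rate_down = $k_perf_loss;
}

node preCTL {
  rate_up = cd8 & TCR_I & CD28 ? $u_preCTL : 0;
  rate_down = 0;
}

node TCR_I {
  rate_up = CD28 & cd8 ? $k_TCR_I : 0;
  rate_down = 0;
}

node TCR_II {
  rate_up = CD28 & cd4 ? $k_TCR_II : 0;
  rate_down = 0;
}

node TGFb_o {
  rate_up = TumorCell | Treg ? $u_TGFb : 0;
  rate_down = $d_TGFb;
}

node TGFb_rec {
  rate_up = cd4_Act ? $k_TGFb_rec : 0;
  rate_down = 0;
}

node Th1 {
  rate_up = cd4_Act & IL12_rec ? $u_Th1 : 0;
  rate_down = 0;
}

node Th17 {
  rate_up = cd4_Act & IL6_rec & TGFb_rec & IL1B_rec ? $u_Th17 : 0;
  rate_down = 0;
}

node Th2 {
  rate_up = cd4_Act & IL4_rec ? $u_Th2 : 0;
  rate_down = 0;
}

node TLR4 {
  rate_up = DC ? $k_TLR4 : 0;
  rate_down = 0;
}

node TNFa_o {
  rate_up = aDC ? $u_TNFa : 0;
  rate_down = $d_TNFa;
}

node TNFa_rec {
  rate_up = TumorCell ? $k_TNFa_rec : 0;
  rate_down = 0;
}

node Treg {
  rate_up = cd4_Act & TGFb_rec ? $u_Treg : 0;
  rate_down = 0;
}

node TumorCell {
  rate_up = 0;
  rate_down = 0;
}

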