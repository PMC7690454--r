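node ActDC {
  rate_up = DC ? $u_ActDC * ($CALR_pop + $ATP_pop + $HMGB1_pop) : 0;
  rate_down = 0;
}

node ATP {
  rate_up = DyingTumorCell ? $u_ATP : 0;
  rate_down = 0;
}

node CALR {
  rate_up = DyingTumorCell ? $u_CALR : 0;
  rate_down = 0;
}

node CTL {
  rate_up = TCell ? $u_CTL : 0;
  rate_down = 0;
}

node DC {
  rate_up = 0;
  rate_down = 0;
}

node Death {
  rate_up = TumorCell ? $kill * $CTL_pop + (DyingTumorCell ? $direct_cyt : 0) : CTL ? $d_CTL : 0;
  rate_down = 0;
}

node Division {
  rate_up = TumorCell & !DyingTumorCell ? $div_tumor : CTL ? $clonal_exp_rate : 0;
  rate_down = 0;
}

node DyingTumorCell {
  rate_up = TumorCell ? $rate_dying : 0;
  rate_down = 0;
}

node HMGB1 {
  rate_up = DyingTumorCell ? $u_HMGB1 : 0;
  rate_down = 0;
}

node LNodeDC {
  rate_up = MigrDC ? $u_LNodeDC : 0;
  rate_down = 0;
}

node MigrDC {
  rate_up = ActDC ? $u_MigrDC : 0;
  rate_down = 0;
}

node TCell {
  rate_up = !TumorCell & !DC ? $u_TCell * $LNodeDC_pop : 0;
  rate_down = 0;
}

node TumorCell {
  rate_up = 0;
  rate_down = 0;
}

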