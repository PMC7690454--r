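death Death;
division Division;
update $ATP_pop = p(ATP);
update $CALR_pop = p(CALR);
update $CTL_pop = p(CTL);
update $HMGB1_pop = p(HMGB1);
update $LNodeDC_pop = p(LNodeDC);
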