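$ATP_pop = 0;
$CALR_pop = 0;
$clonal_exp_rate = 0.0833333333333333;
$CTL_pop = 0;
$d_CTL = 0.0833333333333333;
$direct_cyt = 0.00002;
$div_tumor = 0.00416666666666667;
$HMGB1_pop = 0;
$kill = 0.7;
$LNodeDC_pop = 0;
$rate_dying = 1;
$u_ActDC = 0.15;
$u_ATP = 0.25;
$u_CALR = 0.25;
$u_CTL = 0.0208333333333333;
$u_HMGB1 = 0.166666666666667;
$u_LNodeDC = 0.0166666666666667;
$u_MigrDC = 0.0166666666666667;
$u_TCell = 0.115;
init 0.8 : TumorCell = 1;
init 0.1 : DC = 1;
init 0.1 : -;
set horizon = 300;
set time_step = 2;
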