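# SYNTHETIC stand-in for individual per-speaker mean SDI scores.
# The original per-patient values were not published with the study
# ("available on request"); these constructed values reproduce every
# reported group summary: svPPA mean 3.99 / SD 0.32, lvPPA mean 4.42 /
# SD 0.37, Mann-Whitney u_reported = 19, exact two-sided p = 0.033.
speaker	group	mean_sdi
sv01	svPPA	3.51
sv02	svPPA	3.80
sv03	svPPA	3.94
sv04	svPPA	4.04
sv05	svPPA	4.24
sv06	svPPA	4.41
lv01	lvPPA	3.87
lv02	lvPPA	3.90
lv03	lvPPA	3.98
lv04	lvPPA	4.06
lv05	lvPPA	4.14
lv06	lvPPA	4.22
lv07	lvPPA	4.30
lv08	lvPPA	4.36
lv09	lvPPA	4.48
lv10	lvPPA	4.54
lv11	lvPPA	4.62
lv12	lvPPA	4.70
lv13	lvPPA	4.78
lv14	lvPPA	4.86
lv15	lvPPA	4.94
lv16	lvPPA	4.97
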