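# somnoyoke generator parameters
circ_base = 0.12
siesta_height = 0.55
siesta_center = 7
siesta_width = 2
night_height = 1
night_center = 18
night_width = 3.5
onset_base = 0.012
pressure_gain = 0.00022
pressure_decay = 0.00029
pressure_init = 0.55
pressure_onset_coef = 0.5
pressure_bout_coef = 1.5
bout_meanlog_day = 3.8286413964891
bout_meanlog_night = 4.35670882668959
bout_sdlog = 0.95
active_meanlog = 0.693147180559945
active_sdlog = 0.5
act_morning_height = 0.6
act_evening_height = 1.1
act_peak_width = 1.5
rest_max = 0.8
arousal_prob = 1
hyperactivity_gain = 0.05
hyperactivity_max = 1.5
hyperactivity_halflife_h = 16
seed = 1
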