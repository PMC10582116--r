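condition	mean_female	sd_female	mean_male	sd_male
eyes	0.259	0.085	0.226	0.064
jaw	0.228	0.056	0.187	0.055
lips	0.231	0.066	0.201	0.063
tongue	0.278	0.069	0.264	0.056
upper_arms	0.216	0.079	0.200	0.061
forearms	0.239	0.072	0.209	0.047
wrists	0.302	0.063	0.266	0.062
fingers	0.303	0.068	0.280	0.066
left_leg	0.217	0.085	0.183	0.083
right_leg	0.199	0.096	0.209	0.083
ankles	0.216	0.072	0.188	0.066
toes	0.244	0.070	0.184	0.055
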