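condition	voxels_female	voxels_male	similarity_r
eyes	38843	53649	0.66
jaw	14336	34774	0.56
lips	27593	36828	0.64
tongue	37443	52374	0.64
upper_arms	9434	30045	0.48
forearms	22018	38586	0.60
wrists	26317	47832	0.64
fingers	27359	47557	0.65
left_leg	6267	8892	0.70
right_leg	5325	10933	0.64
ankles	11112	35301	0.51
toes	29737	42820	0.64
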