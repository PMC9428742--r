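activity_name	met_value
walking	3.0
brisk_walking	4.3
jogging	7.0
running	9.8
cycling	6.8
swimming	6.0
aerobics	6.5
yoga	2.5
pilates	3.0
weight_training	3.5
dancing	4.5
hiking	6.0
gardening	3.8
tennis	7.3
elliptical	5.0
stair_climbing	4.0
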