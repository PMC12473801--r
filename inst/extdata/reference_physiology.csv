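# Reference adult physiology (male, 30 y, 73 kg, 176 cm), ICRP-style organ
# volumes and regional blood flows. Cardiac output is the sum of the regional
# arterial flows; lung and the two blood pools carry no regional flow entry
# (lung perfusion equals cardiac output). Version 1.0.
organ,volume_l,flow_l_per_h
lung,0.53,NA
adipose,14.3,19.5
bone,10.5,19.5
brain,1.45,46.8
gut,1.65,58.5
heart,0.33,15.6
kidney,0.31,74.1
liver,1.80,25.4
muscle,28.0,66.3
skin,3.30,19.5
spleen,0.15,7.8
pancreas,0.10,3.9
arterial_blood,1.70,NA
venous_blood,3.50,NA
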