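# Vinardo scoring function: single-Gaussian steric term, hydrophobic onset
# fixed at contact (p1 = 0), revised C/N/O radii. Distances in Angstrom.
# Fluorine kept hydrophobic (Vina convention; see package documentation).
name vinardo
weight_gauss1 -0.045
weight_gauss2 0.0
weight_repulsion 0.800
weight_hydrophobic -0.035
weight_hbond -0.600
gauss1_offset 0.0
gauss1_width 0.8
gauss2_enabled false
hydrophobic_p1 0.0
hydrophobic_p2 2.5
hbond_h1 -0.6
cutoff 8.0
torsion_coeff 0.05846
radius_C 2.0
radius_CA 1.9
radius_N 1.7
radius_O 1.6
radius_S 2.0
radius_P 2.1
radius_F 1.5
radius_Cl 1.8
radius_Br 2.0
radius_I 2.2
radius_Met 1.2
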