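# Vina scoring function: term weights, term parameters, atomic radii.
# Distances in Angstrom; weights dimensionless (energies in kcal/mol-like units).
name vina
weight_gauss1 -0.035579
weight_gauss2 -0.005156
weight_repulsion 0.840245
weight_hydrophobic -0.035069
weight_hbond -0.587439
gauss1_offset 0.0
gauss1_width 0.5
gauss2_enabled true
gauss2_offset 3.0
gauss2_width 2.0
hydrophobic_p1 0.5
hydrophobic_p2 1.5
hbond_h1 -0.7
cutoff 8.0
torsion_coeff 0.05846
# radii: CA = aromatic carbon, Met = any metal
radius_C 1.9
radius_CA 1.9
radius_N 1.8
radius_O 1.7
radius_S 2.0
radius_P 2.1
radius_F 1.5
radius_Cl 1.8
radius_Br 2.0
radius_I 2.2
radius_Met 1.2
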