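# co2mea force-field parameter file
# nonbonded parameters calibrated against the shipped reference dimer energetics (Levenberg-Marquardt, fixed multi-start)
atom C_co2 1.502876486 0.02817118822
atom O_co2 1.489039865 0.1011598184
atom C_sp3 2.04 0.027
atom N_amine 1.519057498 1.250710076
atom O_hydroxyl 1.462215704 2.2
atom H_C 1.62 0.02
atom H_N 1.6 0.018
atom H_O 1.6 0.015
bond C_co2:O_co2 1043.075344 1.16 -1.484321671
bond O_hydroxyl:H_O 520 0.96 2.594569504
bond N_amine:H_N 460 1.01 0.8398259409
bond C_sp3:O_hydroxyl 380 1.42 -2.264771343
bond C_sp3:N_amine 360 1.47 -4.014040521
bond C_sp3:C_sp3 320 1.53 0
bond C_sp3:H_C 330 1.1 0
angle O_co2:C_co2:O_co2 49.28301282 180
angle C_sp3:O_hydroxyl:H_O 55 108.5
angle O_hydroxyl:C_sp3:H_C 55 109.5
angle C_sp3:C_sp3:O_hydroxyl 60 109.5
angle H_C:C_sp3:H_C 40 108
angle C_sp3:C_sp3:H_C 45 110
angle C_sp3:C_sp3:N_amine 60 109.5
angle N_amine:C_sp3:H_C 50 109.5
angle C_sp3:N_amine:H_N 50 109.5
angle H_N:N_amine:H_N 45 106.4
torsion X:C_sp3:C_sp3:X 0 0 0.5
torsion X:C_sp3:O_hydroxyl:X 0 0 0.35
torsion X:C_sp3:N_amine:X 0 0 0.3
global dielectric 1
global cut_vdw 10
global cut_dip 12
global taper 1
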