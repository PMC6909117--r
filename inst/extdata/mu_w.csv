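# Tungsten (Z = 74), density 19.30 g/cm3
# Mass attenuation (mu/rho) coefficients, cm2/g. Values follow NIST SRD 126
# (Hubbell & Seltzer); the K edge at 69.525 keV is represented by the two
# adjacent grid points 69.5/69.6 keV. L-edge structure between 10.2 and
# 12.1 keV is NOT resolved on this grid (log-log interpolation smears it).
# The mu_en/rho column is APPROXIMATE (not NIST-traceable); it is bundled for
# completeness of the table format and is not used in any computation: anode
# self-filtration needs mu/rho only.
energy_kev,mu_rho_cm2_g,mu_en_rho_cm2_g
10,96.91,89.2
15,138.9,122.0
20,65.73,57.0
30,22.73,19.6
40,10.67,9.1
50,5.949,5.05
60,3.713,3.12
69.5,2.552,2.12
69.6,11.23,3.93
80,7.810,3.12
100,4.438,2.00
150,1.581,0.87
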