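# Dry air (near sea level), density 1.205e-3 g/cm3 at 20 C
# Mass attenuation (mu/rho) and mass energy-absorption (mu_en/rho)
# coefficients, cm2/g, at the standard published grid.
# Source: NIST Standard Reference Database 126 (Hubbell & Seltzer),
# "Tables of X-Ray Mass Attenuation Coefficients ... Dry Air".
energy_kev,mu_rho_cm2_g,mu_en_rho_cm2_g
10,5.120,4.742
15,1.614,1.334
20,0.7779,0.5389
30,0.3538,0.1537
40,0.2485,0.06833
50,0.2080,0.04098
60,0.1875,0.03041
80,0.1662,0.02407
100,0.1541,0.02325
150,0.1356,0.02496
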