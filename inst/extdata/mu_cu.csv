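# Copper (Z = 29), density 8.96 g/cm3
# Mass attenuation (mu/rho) and mass energy-absorption (mu_en/rho)
# coefficients, cm2/g, at the standard published grid.
# Source: NIST Standard Reference Database 126 (Hubbell & Seltzer),
# "X-Ray Mass Attenuation Coefficients", element tables.
energy_kev,mu_rho_cm2_g,mu_en_rho_cm2_g
10,215.9,148.4
15,74.05,57.88
20,33.79,27.88
30,10.92,9.349
40,4.862,4.163
50,2.613,2.192
60,1.593,1.290
80,0.7630,0.5581
100,0.4584,0.2949
150,0.2217,0.1027
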