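# Reference half-value layers (mmCu) and effective energies (keV) for a
# 16-channel and a 64-channel MDCT scanner at several tube voltages,
# obtained by three methods: conventional nonrotating (nr), rotating-tube
# copper-pipe measurement (cp_m), and Monte Carlo simulation of the
# copper-pipe geometry (cp_s). Used for method-comparison examples and the
# equivalence-test demonstrations.
scanner,tube_voltage_kv,hvl_nr_mmcu,hvl_cp_m_mmcu,hvl_cp_s_mmcu,energy_nr_kev,energy_cp_m_kev,energy_cp_s_kev
16-channel MDCT,80,0.19,0.19,0.20,42.9,43.1,43.6
16-channel MDCT,110,0.31,0.34,0.32,51.1,52.8,51.9
16-channel MDCT,130,0.41,0.45,0.43,56.8,58.6,57.8
64-channel MDCT,80,0.21,0.20,0.23,44.4,44.0,45.7
64-channel MDCT,100,0.30,0.31,0.33,50.6,51.0,52.3
64-channel MDCT,120,0.41,0.42,0.41,57.0,57.2,56.8
64-channel MDCT,140,0.55,0.54,0.57,63.4,62.6,64.0
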