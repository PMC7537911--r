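# Minimal CaRU model parameters (concentrations uM, time ms,
# volumes as fractions of the unit volume v = v_i + v_sr + v_d)
g      = 2.00892857142857  # DERIVED
tau_i  = 0.1  # DERIVED
g_up   = 0.10848760167346  # DERIVED
K_s    = 0.64  # DERIVED
K_o    = 15  # PAPER
k_p    = 0.0021  # DERIVED
k_m    = 0.4725  # DERIVED
v_i    = 0.977070175438597  # DERIVED
v_sr   = 0.0219298245614035  # DERIVED
v_d    = 0.001  # DERIVED
B_b    = 80  # PAPER
K_b    = 0.5  # PAPER
B_SQ   = 0  # PAPER
K_SQ   = 650  # PAPER
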