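# Multi-layer cortical microcircuit (8 populations, 77169 neurons).
# Companion spiking-model parameter set; indegrees derived from pairwise
# connection probabilities (see package documentation). Units: ms, mV, pA,
# spikes/s. Matrices are row-major, rows = target, columns = source.
labels: [23E, 23I, 4E, 4I, 5E, 5I, 6E, 6I]
sizes: [20683, 5834, 21915, 5479, 4850, 1065, 14395, 2948]
conn_prob:
    - [0.1009000000, 0.1689000000, 0.0437000000, 0.0818000000, 0.0323000000, 0.0000000000, 0.0076000000, 0.0000000000]
    - [0.1346000000, 0.1371000000, 0.0316000000, 0.0515000000, 0.0755000000, 0.0000000000, 0.0042000000, 0.0000000000]
    - [0.0077000000, 0.0059000000, 0.0497000000, 0.1350000000, 0.0067000000, 0.0003000000, 0.0453000000, 0.0000000000]
    - [0.0691000000, 0.0029000000, 0.0794000000, 0.1597000000, 0.0033000000, 0.0000000000, 0.1057000000, 0.0000000000]
    - [0.1004000000, 0.0622000000, 0.0505000000, 0.0057000000, 0.0831000000, 0.3726000000, 0.0204000000, 0.0000000000]
    - [0.0548000000, 0.0269000000, 0.0257000000, 0.0022000000, 0.0600000000, 0.3158000000, 0.0086000000, 0.0000000000]
    - [0.0156000000, 0.0066000000, 0.0211000000, 0.0166000000, 0.0572000000, 0.0197000000, 0.0396000000, 0.2252000000]
    - [0.0364000000, 0.0010000000, 0.0034000000, 0.0005000000, 0.0277000000, 0.0080000000, 0.0658000000, 0.1443000000]
indegrees:
    - [2199.8648594621, 1079.3200600510, 979.2412678092, 467.5781148761, 159.2408105577, 0.0000000000, 109.8198452476, 0.0000000000]
    - [2990.0058309232, 860.2610304156, 703.6918249787, 289.6938452637, 380.7358003786, 0.0000000000, 60.5863202070, 0.0000000000]
    - [159.8754144043, 34.5225416137, 1117.1731373381, 794.5961990566, 32.6043468507, 0.3195479279, 667.3251932627, 0.0000000000]
    - [1480.9735010248, 16.9431792508, 1813.0202134264, 953.3257548024, 16.0314661763, 0.0000000000, 1608.1228672894, 0.0000000000]
    - [2188.3660145563, 374.6511448794, 1135.6297903023, 31.3196454142, 420.7707806824, 496.4720489771, 296.6946792617, 0.0000000000]
    - [1165.6676630208, 159.0839912547, 570.5792469809, 12.0670776283, 300.0956789232, 404.1726536706, 124.3323948351, 0.0000000000]
    - [325.1979889771, 38.6320261848, 467.3546148714, 91.7147554534, 285.6703713059, 21.1899120779, 581.6359429664, 752.1832171280]
    - [766.9051199415, 5.8369187761, 74.6379557945, 2.7401850169, 136.2407641238, 8.5542614954, 979.7917921920, 459.4028259846]
K_ext: [1600, 1500, 2100, 1900, 2000, 1900, 2900, 2100]
r_ext: 8.0
PSC_amp_pA: 87.8
g: 4.0
weight_rel:
  # relative synaptic weights (multiples of the reference excitatory PSC);
  # the 4E -> 2/3E projection has doubled weight
    - [1.0000000000, -4.0000000000, 2.0000000000, -4.0000000000, 1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000]
    - [1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000]
    - [1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000]
    - [1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000]
    - [1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000]
    - [1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000]
    - [1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000]
    - [1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000, 1.0000000000, -4.0000000000]
delay_mean_ms:
    - [1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000]
    - [1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000]
    - [1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000]
    - [1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000]
    - [1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000]
    - [1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000]
    - [1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000]
    - [1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000, 1.5000000000, 0.7500000000]
delay_std_ms:
    - [0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000]
    - [0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000]
    - [0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000]
    - [0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000]
    - [0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000]
    - [0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000]
    - [0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000]
    - [0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000, 0.7500000000, 0.3750000000]
neuron:
  tau_m_ms: 10.0
  tau_s_ms: 0.5
  tau_ref_ms: 2.0
  C_m_pF: 250.0
  V_th_mV: 15.0
  V_reset_mV: 0.0
modifications:
  # stabilising modifications applied by the loader (modified = TRUE)
  scale_K_4E_from_4I: 0.85
  scale_K_ext_4E: 0.81
  delay_std_all_ms: 1.0

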