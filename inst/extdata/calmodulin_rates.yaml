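# Cooperative Ca2+ binding constants for calmodulin.
#
# Scheme: two independent lobes (N-terminal, C-terminal), each binding two
# calcium ions sequentially; the constants are the macroscopic rates of the
# first (T) and second (R) binding step of each lobe, so the second-site
# affinity exceeds the first (positive cooperativity).
#
# Provenance: Faas GC, Raghavachari S, Lisman JE, Mody I (2011)
# "Calmodulin as a direct detector of Ca2+ signals", Nat Neurosci 14:301-304
# (two-step sequential binding model fitted to stopped-flow data).
#
# Units: k_on in M^-1 s^-1, k_off in s^-1.
version: 1
N_lobe:
  k_on1: 7.7e+8
  k_off1: 1.6e+5
  k_on2: 3.2e+10
  k_off2: 2.2e+4
C_lobe:
  k_on1: 8.4e+7
  k_off1: 2.6e+3
  k_on2: 2.5e+7
  k_off2: 6.5
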