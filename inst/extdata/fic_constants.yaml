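# Fixed biophysical constants of the reduced Wong-Wang (dynamic mean-field)
# model with feedback inhibition control, Deco et al. (2014) formulation.
# Units: currents nA, rates Hz, time s. Versioned so an alternative
# transcription can be swapped in without touching code.
version: deco2014-v1
a_E: 310.0      # excitatory gain (nC^-1)
b_E: 125.0      # excitatory threshold (Hz)
d_E: 0.16       # excitatory curvature (s)
a_I: 615.0      # inhibitory gain (nC^-1)
b_I: 177.0      # inhibitory threshold (Hz)
d_I: 0.087      # inhibitory curvature (s)
tau_E: 0.1      # NMDA gating time constant (s)
tau_I: 0.01     # GABA gating time constant (s)
gamma: 0.641    # excitatory kinetic rate (dimensionless, t in s, r in Hz)
J_NMDA: 0.15    # long-range NMDA coupling (nA)
I_0: 0.382      # background current (nA)
W_E: 1.0        # background scaling, excitatory population
W_I: 0.7        # background scaling, inhibitory population
w_II: 1.0       # inhibitory-to-inhibitory weight (nA), fixed, not optimized
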