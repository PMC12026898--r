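# Balloon-Windkessel hemodynamic constants, Friston et al. (2003) values
# with the Obata-corrected BOLD readout weights. Units: s^-1 for rates,
# s for transit time; the rest dimensionless.
version: friston2003-v1
kappa: 0.65     # vasodilatory signal decay (s^-1)
gamma_h: 0.41   # flow-dependent feedback (s^-1)
tau_h: 0.98     # hemodynamic transit time (s)
alpha: 0.32     # vessel stiffness exponent (Grubb)
rho: 0.34       # resting oxygen extraction fraction
V0: 0.02        # resting venous volume fraction
k1: 2.38        # BOLD weight 7*rho
k2: 2.0         # BOLD weight
k3: 0.48        # BOLD weight 2*rho - 0.2
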