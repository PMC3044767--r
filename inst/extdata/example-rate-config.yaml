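# Example configuration for the ring rate model: a hypercolumn whose
# projection widths are derived from the contrast-invariance conditions
# ("design") and whose inhibitory self-coupling sits near the boundary
# between saturating and supersaturating contrast-response shapes.
model: rate
populations:
  E: {N: 100, tau: 10, gain: 1, beta: 1.5}
  I: {N: 100, tau: 10, gain: 3, beta: 2.2}
connectivity:
  J_EE: 5
  J_IE: 3
  J_EI: 5.6
  J_II: 4.3
  widths: design
drive:
  sigma_E: 18.37
  sigma_I: 22.25
  nu0: 1.5
solver:
  dt: 1
  tol: 1.0e-10
  damping: 0.5
seeds:
  master: 1
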