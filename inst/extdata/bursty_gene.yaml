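# Bursty self-regulated gene expression with the canonical parameter set:
# Hill-regulated burst production (mean continuum burst size b = B/omega),
# first-order protein decay.
species:
  - {name: protein, domain_max: 6, n_cells: 120}
params: {r0: 2, r1: 10, "n": 4, gamma0: 1, b: 0.2}
reactions:
  - {displacement: [-1], rate: "gamma0*x", name: decay}
jumps:
  - direction: [1]
    rate: "hill(x, r0, r1, n)"
    kernel: {type: exponential, b: 0.2}
    mode: probability
    name: burst
omega: 200
diffusion: false
solver: {t_final: 20, method: ssprk3}
initial: {type: uniform}
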