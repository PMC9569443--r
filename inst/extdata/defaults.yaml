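# Pipeline defaults; CLI flags override individual values.
tol_ppm: 10        # XIC m/z tolerance (ppm), applied at every selection level
integration: trapezoid
loq_ratio: 0.01    # light/heavy ratio below which an analyte is detect-only
noise_floor: 0     # area at/below which a signal counts as absent
seed: 1
replicates: 3
cycle_s: 1         # acquisition cycle time (seconds)
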