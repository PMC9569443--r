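# Built-in modification registry (monoisotopic deltas, Da).
# target: C = any cysteine; cterm-C = C-terminal cysteine only;
# loss = neutral-loss species, not a residue modification.
- name: carbamidomethyl
  target: C
  delta: 57.021464
- name: o_methyl
  target: cterm-C
  delta: 14.015650
- name: farnesyl
  target: cterm-C
  delta: 204.187801
- name: water
  target: loss
  delta: 18.010565
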