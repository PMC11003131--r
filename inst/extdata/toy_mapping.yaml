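# Toy three-bead mapping of a 9-atom chain molecule, with a ground-truth
# block usable by the synthetic trajectory generator. The mapping schemes of
# real additives are user-suppliable configs in exactly this schema.
molecule: toy-chain
atoms:
  - {name: C1, element: C}
  - {name: C2, element: C}
  - {name: C3, element: C}
  - {name: C4, element: C}
  - {name: C5, element: C}
  - {name: C6, element: C}
  - {name: N1, element: "N"}   # quote N/Y: bare YAML booleans
  - {name: O1, element: O}
  - {name: O2, element: O}
beads:
  - {name: B1, type: C1T, atoms: [C1, C2, C3]}
  - {name: B2, type: C1T, atoms: [C4, C5, C6]}
  - {name: B3, type: P4T, atoms: [N1, O1, O2], weighting: mass}
bonds:
  - [B1, B2]
  - [B2, B3]
angles:
  - [B1, B2, B3]
ground_truth:
  bonds:
    - {term: [B1, B2], mean: 0.47, sigma: 0.02}
    - {term: [B2, B3], mean: 0.37, sigma: 0.015}
  angles:
    - {term: [B1, B2, B3], mean: 130, sigma: 8}
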