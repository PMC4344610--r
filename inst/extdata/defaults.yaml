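# Default configuration shipped with glycotorsion: Karplus parameterizations,
# the idealized Fuc-GlA linkage spec, and the conformer-state set.
karplus:
  tvaroska1989: {A: 5.7, B: -0.6, C: 0.5}
linkage:
  name: Fuc-GlA
  phi_atoms: [H1, C1, O, CX]
  psi_atoms: [C1, O, CX, HX]
  aglycon_position: 3
conformer_states:
  radius: 35
  states:
    - {label: I, phi: 30, psi: 40}
    - {label: II, phi: 30, psi: 0}
    - {label: III, phi: 30, psi: 180}
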