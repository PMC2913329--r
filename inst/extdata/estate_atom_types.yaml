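# Default atom-type (E-state fragment) count descriptors: 21 Kier-Hall style
# environments over C/N/O/halogen chemistry. Each entry pins down an element
# plus its full bonding signature (attached hydrogens; counts of single,
# double, triple and aromatic bonds to heavy atoms), so the types are
# pairwise disjoint by construction. Exact parity with any externally
# published 21-descriptor list requires loading that list here instead.
- {name: sCH3,  element: C, aromatic: false, nh: 3, single: 1}
- {name: ssCH2, element: C, aromatic: false, nh: 2, single: 2}
- {name: sssCH, element: C, aromatic: false, nh: 1, single: 3}
- {name: ssssC, element: C, aromatic: false, nh: 0, single: 4}
- {name: dCH2,  element: C, aromatic: false, nh: 2, double: 1}
- {name: dsCH,  element: C, aromatic: false, nh: 1, single: 1, double: 1}
- {name: dssC,  element: C, aromatic: false, nh: 0, single: 2, double: 1}
- {name: aaCH,  element: C, aromatic: true,  nh: 1, aromatic_bonds: 2}
- {name: aasC,  element: C, aromatic: true,  nh: 0, single: 1, aromatic_bonds: 2}
- {name: aaaC,  element: C, aromatic: true,  nh: 0, aromatic_bonds: 3}
- {name: sNH2,  element: N, aromatic: false, nh: 2, single: 1}
- {name: ssNH,  element: N, aromatic: false, nh: 1, single: 2}
- {name: sssN,  element: N, aromatic: false, nh: 0, single: 3}
- {name: dsN,   element: N, aromatic: false, nh: 0, single: 1, double: 1}
- {name: aaN,   element: N, aromatic: true,  nh: 0, aromatic_bonds: 2}
- {name: sOH,   element: O, aromatic: false, nh: 1, single: 1}
- {name: dO,    element: O, aromatic: false, nh: 0, double: 1}
- {name: ssO,   element: O, aromatic: false, nh: 0, single: 2}
- {name: aaO,   element: O, aromatic: true,  nh: 0, aromatic_bonds: 2}
- {name: sCl,   element: Cl, aromatic: false, nh: 0, single: 1}
- {name: sBr,   element: Br, aromatic: false, nh: 0, single: 1}
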