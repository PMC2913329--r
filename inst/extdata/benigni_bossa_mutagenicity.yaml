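# Structural-alert rulebase for Ames mutagenicity.
# Thirty rules in the Benigni/Bossa (Toxtree) lineage covering the classic
# electrophilic and pro-electrophilic toxicophores. SMARTS are a best-effort
# re-encoding of the published rule descriptions and are meant to be edited:
# drop in your own patterns, exceptions, or an explicit partition block
# (enhancing: [...] / suspicious: [...]) to override the trained selection.
#
# literature_fp_rate_zero marks rules reported with a nominal false-positive
# rate of 0% in their source literature; such rules may be admitted to the
# enhancing set even when their data support is below the audit threshold.
alerts:
  - alert_id: sa01
    name: acyl halide
    patterns: ["[CX3](=O)[F,Cl,Br,I]"]
    literature_fp_rate_zero: true
    provenance: direct-acting acylating electrophile
  - alert_id: sa02
    name: alkyl or benzyl ester of sulfonic/phosphonic acid
    patterns:
      - "[CH3,CH2X4][OX2][SX4](=[OX1])=[OX1]"
      - "[CH3,CH2X4][OX2][PX4]=[OX1]"
    literature_fp_rate_zero: true
    provenance: alkylating ester electrophile
  - alert_id: sa03
    name: N-methylol derivative
    patterns: ["[NX3][CH2][OX2H1]"]
    literature_fp_rate_zero: true
    provenance: formaldehyde releaser
  - alert_id: sa04
    name: monohaloalkene
    patterns: ["[F,Cl,Br,I][CX3]=[CX3]"]
    provenance: vinyl halide, metabolic epoxidation
  - alert_id: sa05
    name: nitrogen or sulfur mustard
    patterns: ["[F,Cl,Br,I][CH2][CH2][NX3,SX2][CH2][CH2][F,Cl,Br,I]"]
    literature_fp_rate_zero: true
    provenance: bis(2-haloethyl) alkylator
  - alert_id: sa06
    name: propiolactone or propiosultone
    patterns:
      - "O=C1OCC1"
      - "O=S1(=O)OCC1"
    literature_fp_rate_zero: true
    provenance: strained-ring alkylating lactone/sultone
  - alert_id: sa07
    name: epoxide or aziridine
    patterns:
      - "[CX4]1[OX2][CX4]1"
      - "[CX4]1[NX3][CX4]1"
    provenance: strained three-membered electrophile
  - alert_id: sa08
    name: aliphatic halide
    patterns: ["[CX4][Cl,Br,I]"]
    provenance: SN2 alkylating agent
  - alert_id: sa09
    name: alkyl nitrite
    patterns: ["[CX4][OX2][NX2]=[OX1]"]
    provenance: nitrosating agent
  - alert_id: sa10
    name: alpha,beta-unsaturated carbonyl
    patterns: ["[CX3]=[CX3][CX3]=[OX1]"]
    provenance: Michael acceptor
  - alert_id: sa11
    name: simple aldehyde
    patterns: ["[CX3H1](=O)[#6]"]
    provenance: Schiff-base former
  - alert_id: sa12
    name: quinone
    patterns:
      - "O=C1C=CC(=O)C=C1"
      - "O=C1C=CC(=O)c2ccccc12"
      - "O=C1c2ccccc2C(=O)c2ccccc21"
    provenance: redox-cycling Michael acceptor
  - alert_id: sa13
    name: hydrazine
    patterns: ["[NX3][NX3]"]
    exceptions: ["[NX3][NX3][CX3]=[OX1]"]
    provenance: N-N single bond, radical/diazonium precursor
  - alert_id: sa14
    name: aliphatic azo or azoxy
    patterns:
      - "[CX4][NX2]=[NX2][CX4]"
      - "[NX2]=[NX3+][OX1-]"
      - "[NX2]=[NX3]=[OX1]"
    provenance: azoalkane, carbocation precursor
  - alert_id: sa15
    name: isocyanate or isothiocyanate
    patterns:
      - "[NX2]=C=[OX1]"
      - "[NX2]=C=[SX1]"
    literature_fp_rate_zero: true
    provenance: carbamoylating electrophile
  - alert_id: sa16
    name: alkyl carbamate
    patterns: ["[NX3][CX3](=[OX1])[OX2][CX4]"]
    literature_fp_rate_zero: true
    provenance: carbamoylating agent
  - alert_id: sa17
    name: alkyl hydroperoxide or peroxide
    patterns: ["[#6][OX2][OX2]"]
    provenance: radical-generating peroxide
  - alert_id: sa18
    name: polycyclic aromatic hydrocarbon
    patterns:
      - "c1ccc2cc3ccccc3cc2c1"
      - "c1ccc2ccc3ccccc3c2c1"
    provenance: PAH, diol-epoxide metabolic activation
  - alert_id: sa19
    name: heterocyclic polycyclic aromatic
    patterns:
      - "c1ccc2nc3ccccc3cc2c1"
      - "c1ccc2c(c1)[nH]c1ccccc12"
    provenance: aza-PAH
  - alert_id: sa20
    name: nitrogen mustard-like beta-haloethylamine
    patterns: ["[NX3][CH2][CH2][Cl,Br,I]"]
    provenance: aziridinium precursor
  - alert_id: sa21
    name: N-nitrosamine
    patterns: ["[NX3]([#6])([#6])[NX2]=[OX1]"]
    provenance: alpha-hydroxylation to diazonium
  - alert_id: sa22
    name: azide or triazene
    patterns:
      - "[NX2]=[NX2+]=[NX1-]"
      - "[#6][NX2]=[NX2][NX3]"
    literature_fp_rate_zero: true
    provenance: diazonium precursor
  - alert_id: sa23
    name: aliphatic N-nitro
    patterns:
      - "[NX3][NX3+](=[OX1])[OX1-]"
      - "[NX3][NX3](=[OX1])=[OX1]"
    literature_fp_rate_zero: true
    provenance: nitramine
  - alert_id: sa24
    name: alpha-haloether or alpha-halothioether
    patterns: ["[OX2,SX2][CX4][Cl,Br,I]"]
    literature_fp_rate_zero: true
    provenance: oxocarbenium-forming alkylator
  - alert_id: sa25
    name: aromatic nitroso
    patterns: ["a[NX2]=[OX1]"]
    provenance: reactive C-nitroso arene
  - alert_id: sa26
    name: aromatic ring N-oxide
    patterns: ["[n+][O-]"]
    provenance: heteroaromatic N-oxide
  - alert_id: sa27
    name: aromatic nitro
    patterns:
      - "a[N+](=[OX1])[OX1-]"
      - "a[N](=[OX1])=[OX1]"
    provenance: nitroreduction to hydroxylamine
  - alert_id: sa28
    name: primary aromatic amine
    patterns: ["a[NX3H2]"]
    exceptions: ["[NX3H2]c1ccc(cc1)[SX4](=[OX1])(=[OX1])[OX2H1,OX1-]"]
    provenance: N-hydroxylation to nitrenium; sulfonated anilines excepted
  - alert_id: sa29
    name: aromatic hydroxylamine or N-acyloxy amine
    patterns:
      - "a[NX3H1][OX2H1]"
      - "a[NX3H1][OX2][CX3]=[OX1]"
    provenance: proximate nitrenium precursor
  - alert_id: sa30
    name: coumarin or furocoumarin
    patterns:
      - "O=c1ccc2ccccc2o1"
      - "O=C1C=Cc2ccccc2O1"
    provenance: photoactivated DNA adduct former
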