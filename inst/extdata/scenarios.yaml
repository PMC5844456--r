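# Six origin hypotheses for quinone evolution in Opiliones scent glands,
# encoded as edge-constrained reconstructions. Each scenario lists named
# origin GROUPS: gains (absent -> present) are permitted only on the edges
# above the listed clades/leaves; "root_stem" means the virtual stem above
# the root. A group with several edges counts as ONE origin (used where the
# taxa said to share an origin are not sister on the composite tree: the
# dyspnoan naphthoquinone producers are nemastomatines + Hesperonemastoma).
# The schematic panels are mapped to clades here; the file is editable.
- label: NQ-A
  character: NQ_class
  required: true
  origins:
    cyphophthalmi: [Cyphophthalmi]
    dyspnoi: [Nemastomatinae, Hesperonemastoma_modestum]
    phalangiid: [Phalangiidae]
- label: NQ-B
  character: NQ_class
  required: true
  origins:
    cyphophthalmi: [Cyphophthalmi]
    palpatores: [Palpatores]
- label: NQ-C
  character: NQ_class
  required: true
  origins:
    opiliones: [root_stem]
- label: BQ-D
  character: BQ_class
  required: true
  origins:
    gonyleptoidea: [Gonyleptoidea]
    gyantinae: [Gyantinae]
    dicranopalpus_group: [Dicranopalpus_group]
    phalangiid: [Phalangiidae]
- label: BQ-E
  character: BQ_class
  required: true
  origins:
    palpatores: [Palpatores]
    gonyleptoidea: [Gonyleptoidea]
- label: BQ-F
  character: BQ_class
  required: true
  origins:
    phalangida: [Phalangida]
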