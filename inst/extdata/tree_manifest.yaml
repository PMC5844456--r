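# Checked-in manifest for the composite Opiliones tree fixture.
# Encodes the figure-legend conventions: suborders as
# (Cyphophthalmi,(Laniatores,(Eupnoi,Dyspnoi))); Phalangioidea as a polytomy
# of its five groups plus Protolophidae (placement of Protolophidae is this
# package's decision -- the legend's five groups omit it although it is
# sampled); phalangiid and sclerosomatid subfamilies, and multi-species
# genera, as polytomies. Taxa with no chemical data anywhere are single
# placeholder leaves (coded missing when bound to characters).
n_leaves: 90
root_children: [Cyphophthalmi, Phalangida]
placeholders:
  - Caddoidea_placeholder
  - Neopilionidae_placeholder
  - Monoscutidae_placeholder
  - Acropsopilionidae_placeholder
  - Nipponopsalididae_placeholder
polytomy_degrees:
  Cyphophthalmi: 3
  Gonyleptoidea: 4
  Phalangioidea: 6
  Phalangiidae: 4
  Oligolophinae: 4
  Platybuninae: 3
  Megabunus: 5
  Opilio: 5
  Sclerosomatidae: 3
  Leiobunum: 7
  Sclerosomatinae: 4
  Sabaconidae: 3
  Nemastomatinae: 7
  Nemastoma: 9
  Ortholasma: 4
clade_tip_counts:
  Cyphophthalmi: 4
  Laniatores: 8
  Gonyleptoidea: 4
  Eupnoi: 43
  Phalangiidae: 21
  Sclerosomatidae: 15
  Gyantinae: 2
  Dicranopalpus_group: 2
  Dyspnoi: 35
  Nemastomatinae: 19
  Palpatores: 78
  Phalangida: 86
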