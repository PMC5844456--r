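---
title: "Tracing secretion chemistry on phylogenies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing secretion chemistry on phylogenies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemotrace)
```

# The problem

Harvestmen (Opiliones) carry a pair of prosomal scent glands, a synapomorphy
of the order: every species in every suborder has the homologous system, and
its defensive secretion chemistry is strongly lineage-specific. That makes
the glands a natural substrate for *phylogenetic chemosystematics*: treat the
ability to produce a compound class as a heritable binary character of a
terminal, map it on a phylogeny, and reconstruct where the trait was gained
and lost. `chemotrace` implements that pipeline end to end for
presence/absence screening data: from GC-MS peak identification, through
character compilation, to ancestral-state reconstruction and explicit
hypothesis ranking. The packaged case study concerns the two quinone
classes of harvestman secretions -- naphthoquinones (NQs) and benzoquinones
(BQs).

# From chromatograms to characters

## Retention-index identification

Compounds in the detection tables were identified by Kovats retention index
plus diagnostic EI fragments. For a peak at time $t_x$ bracketed by
$n$-alkanes with carbon numbers $n_0 < n_1$ eluting at $t_{n_0}, t_{n_1}$,

$$RI_x = 100\,n_0 + 100\,(n_1 - n_0)\,\frac{t_x - t_{n_0}}{t_{n_1} - t_{n_0}}.$$

Linear (not logarithmic) interpolation is used because it is the correct
form under a linear oven temperature programme; an alkane itself indexes to
exactly $100n$, and the index is invariant under affine rescaling of the
time axis (both properties are tested). `identify_compound()` accepts a
candidate when $|RI_{\text{peak}} - RI_{\text{lib}}| \le$ `ri_tol` and at
least `min_ion_frac` of the library's diagnostic ions occur among the peak
ions (set membership at unit m/z tolerance). The source study states no
numeric match tolerance, so the defaults are this package's choice:
`ri_tol = 10` index units is conservative -- the closest isomer pair in the
packaged library is 41 units apart -- and `min_ion_frac = 0.5` tolerates
weak fragments without admitting unrelated spectra. Intensity-weighted
spectral similarity is deliberately out of scope; so is extrapolation
beyond the alkane ladder (the usual C9--C36 mix spans all analytes; an
opt-in flag enables it with a warning).

```{r}
identify_compound(2277, c(236, 235, 221, 207), quinone_library())
```

## Coding policy

Screening tables use five cell states: detected, not detected, partial
(found in part of the analysed material only), inconclusive, and missing.
`binarize()` collapses them per taxon and per character:

* any *detected* or *partial* cell among the character's compounds makes it
  **present** -- a partial detection is still positive evidence that the
  terminal can synthesise the compound;
* otherwise any *not detected* cell makes it **absent**;
* otherwise (inconclusive/missing evidence only) the character is
  **missing**.

The default policy emits `NQ_class` (NQ, MNQ, MOQ, MMOQ, ND, CNQ) and
`BQ_class` (BQ, ABQ). Three choices deserve a note. The naphthalenediol ND
is grouped with the naphthoquinones: it is the redox partner of NQ and
co-occurs with NQs wherever it was recorded. Anthraquinones are compiled
but excluded from the default characters, because the reconstruction
question concerns the NQ and BQ classes; `include_anthraquinones = TRUE`
adds an `AQ_class`. Cells printed as "data missing" code to *missing*, not
*absent* -- absence of evidence is kept distinct from evidence of absence.
All of this is overridable via `coding_policy()`.

# The reconstruction model

## Asymmetric-cost parsimony

`sankoff()` performs minimum-cost ancestral-state reconstruction under an
arbitrary step matrix by the standard dynamic programme over the rooted
tree: for node $v$ and state $s$,

$$S_v(s) = \sum_{c \in \mathrm{children}(v)} \min_t \big[ c(s, t) + S_c(t) \big],$$

with leaf rows $0$ at the observed state and $\infty$ elsewhere. The
default step matrix charges a gain (absent $\to$ present) 2 and a loss
(present $\to$ absent) 1. The asymmetry encodes biosynthesis: acquiring a
compound class needs a hierarchical multi-step pathway, while a loss can
follow from inactivating a single enzyme, so convergent gains should be
penalised relative to losses. The 2:1 ratio is the established
chemosystematic convention and is a parameter (`step_matrix(gain, loss)`),
not a constant.

Four further modelling decisions:

* **Virtual stem.** By default a pre-root stem fixed to `absent` is added,
  so a character already present at the root is charged as a gain on the
  stem. Quinones are innovations of the harvestman lineage; an origin at
  the root must still count as an origin. `stem_state = NULL` gives the
  free-root variant for sensitivity analysis.
* **Hard polytomies.** Multifurcations contribute additively over all
  children and are never resolved or enumerated; the composite tree's
  polytomies represent simultaneous divergence as published.
* **Missing leaves** get zero cost in every state -- the standard Sankoff
  treatment. Their imputed states are reported but uninformative, and
  adding a missing leaf anywhere provably never changes the optimum
  (property-tested).
* **Exact arithmetic.** Costs are kept as integer-valued doubles and sums
  of such; no tolerance enters any comparison.

## MPR enumeration and origin counting

All most-parsimonious reconstructions are recovered by backtracking, in a
deterministic order (root states in step-matrix order, then depth-first
along the preorder edge sequence) -- determinism over biology. Enumeration
is capped (`mpr_cap`, default 10000) and truncation is flagged, never
silent. Gains and losses are read off each MPR's edges, the stem included.

The *range* of gain counts over all MPRs is computed exactly without
enumeration, by a lexicographic rescaling: multiply all costs by a constant
$K$ exceeding any achievable gain count and add (subtract) one unit to the
gain entry; the DP then minimises cost first and gains second, yielding the
minimum (maximum) origins at optimum. This also makes the origin range
valid when the MPR list is truncated.

## Scenario ranking

Competing origin hypotheses are encoded as *scenarios*: named origin
groups, each a set of tree edges on which gains are permitted; everywhere
else the gain cost is set to $\infty$ (losses stay unconstrained, since the
hypotheses constrain origins only). A group with several edges represents
one hypothesised origin whose bearers are not sister on the working tree
and counts once -- the packaged NQ-A scenario encodes the dyspnoan origin
as two allowed edges (nemastomatines and *Hesperonemastoma*) for exactly
this reason. When a scenario is `required`, minimum-cost reconstructions
missing a gain in some group are rejected; the check applies among
minimum-cost constrained solutions, a deliberate simplification documented
here (a hypothetical scenario satisfiable only above its constrained
optimum would report as infeasible rather than return a suboptimal
reconstruction). Infeasibility is a result, not an error.
`compare_scenarios()` ranks scenarios of one character by constrained cost,
which can never undercut the unconstrained optimum.

```{r}
bound <- bind_characters(opiliones_tree(), binarize(opiliones_detections()))
nq <- Filter(function(s) s$character == "NQ_class", opiliones_scenarios())
compare_scenarios(bound, nq)
```

An honest caveat on the packaged case study: on this tree encoding, coded
strictly from the printed screening tables, the *unconstrained*
naphthoquinone optimum uses several gain edges and costs less than the
single-origin scenario (run the chunk above to see both numbers). The
published preference for a single early acquisition rested on unprinted
encoding choices in the original analysis software; this package therefore
reports the single-origin hypothesis as a constrained, costed scenario
(NQ-C) and the unconstrained min/max origin counts as computed, rather
than asserting the single origin as an MPR property.

# The composite tree fixture

The packaged 90-leaf tree combines published group-level phylogenies under
the generally accepted suborder backbone
(Cyphophthalmi,(Laniatores,(Eupnoi + Dyspnoi))). Phalangioidea is a
polytomy of its five published groups; phalangiid and sclerosomatid
subfamilies, and every multi-species genus, are polytomies; Gonyleptoidea
nests inside Grassatores. Two encoding decisions are this package's own,
flagged in `tree_manifest.yaml`: Protolophidae (sampled, but absent from
the five published groups) joins the Phalangioidea polytomy, and the five
families with no chemical data anywhere (Caddoidea, Neopilionidae,
Monoscutidae, Acropsopilionidae, Nipponopsalididae) enter as single
placeholder leaves coded missing -- they cannot change any optimum but keep
the sampling gaps visible. The manifest pins the leaf set, polytomy
degrees and clade sizes, and the fixture is tested against it.

# What the simulator does and does not emulate

`simulate_history()` runs a two-state continuous-time Markov chain (gain
rate `q01`, loss rate `q10` per unit branch length) root-to-tips from
state absent, drawing exact event times per edge, so the full true history
is available, not just tip patterns. A CTMC rather than per-edge Bernoulli
flips was chosen so the asymmetric-rate regime analogous to the 2:1 step
matrix is expressible; all generators are seed-deterministic and record
their seed. `make_detection_fixture()` dresses simulated tip states as a
detection table (one detected compound per present tip, optional
inconclusive-cell noise) and round-trips exactly through `binarize()` at
zero noise; `make_gc_fixture()` back-computes retention times so that
`kovats_ri()` recovers each library RI exactly. Random test trees come
from `sim_polytomy_tree()`, which collapses internal edges with a set
probability to exercise the hard-polytomy code path.

The simulator emulates presence/absence evolution and table structure. It
does not emulate real screening pathologies -- compound misidentification,
within-species polymorphism beyond the partial state, correlated missing
data, intensity-dependent detection limits -- so passing recovery
experiments validate the reconstruction machinery, not the field
reliability of any particular data set.

`recovery_experiment()` compares the reconstructed minimum origin count
with the simulated truth over a rate grid. Two regimes are asserted in the
test suite: with losses impossible (`q10 = 0`) parsimony can only merge
origins, so the reconstructed minimum never exceeds the truth; and in the
conditioned single-gain regime recovery is exact in every replicate. At
symmetric high rates recovery fractions are reported, not asserted.

# Problem sizes and numerical choices

Validation runs at deliberately modest sizes chosen to make the exhaustive
checks exact: the DP-versus-brute-force battery uses 500 random instances
with 4--8 leaves (small enough to enumerate all internal assignments), the
Fitch cross-check uses random binary trees to 14 leaves, and the
single-gain recovery experiment uses 10,000 replicates on a 16-leaf
polytomy tree. The case-study tree (90 leaves, 2 states) is far below any
performance ceiling of the DP, which is linear in edges times quadratic in
states. Ties in candidate ranking and MPR enumeration always break
deterministically (compound code; state order then preorder index), so
identical inputs give byte-identical outputs.

# Known limitations

* Parsimony only: no likelihood or stochastic mapping, no use of branch
  lengths, by design -- the method matches the data's resolution
  (presence/absence at terminals, composite tree without meaningful branch
  lengths).
* Character independence: NQ and BQ classes are reconstructed separately;
  shared biosynthetic steps between classes are not modelled.
* The `required` check of scenarios applies among minimum-cost constrained
  reconstructions (see above).
* Peak identification is RI window + ion set membership; co-eluting isomers
  with identical fragments (the packaged dimethyl-anthraquinone pair
  differs by 41 RI units) are separable only by RI.
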