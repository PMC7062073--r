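---
title: "mitoskew: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitoskew: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of what it computes, which
modelling choices were open, and what a green test does and does not
establish.

## Coordinates, architecture statistics

All interfaces use 1-based inclusive coordinates on the circular
molecule, the convention of published mitogenome organization tables.
A feature spanning the origin has `start > end` and
`wraps_origin = TRUE`.

The spacer between adjacent features is
`spacer = next.start − prev.end − 1`, including the pair that wraps
through the origin; negative values are overlaps.  Overlap counting is
purely positional (strand-blind), matching the IGR-column semantics of
comparative tables.  This yields the exact identity
`sum(feature spans) + sum(spacers) = genome length` for any circular
annotation, which the tests assert on both the shipped table and
simulated genomes.

Printed `size`/`IGR` columns in input tables are treated as advisory:
recomputed values take precedence and disagreements are surfaced as
warnings, never silently reconciled.  The shipped example table
contains two such rows (a control region whose printed size is one
less than its coordinate span, and one protein-coding gene whose
printed size does not match its coordinates); both printed values are
retained and reported.  Similarly, the "largest overlap" statistic is
reported twice — globally (where two 9-bp tRNA overlaps win) and
restricted to protein-coding-gene pairs (7 bp) — because the two
readings genuinely differ on real tables.

### Gene orders

A gene order is the signed circular permutation of gene labels in
coordinate order (sign = strand).  Equality is rotation-invariant;
reflections are **not** identified, because reading the molecule from
the other strand is a biologically meaningful difference (it flips
every skew).  The control region is excluded by default (gene-order
comparisons conventionally cover genes; the `include_cr` flag exposes
the alternative).  The breakpoint distance counts signed adjacencies
of one order absent from the other, after restricting both orders to
the shared label set — isopod mitogenomes frequently lack tRNAs, and
dropping unshared labels (with a warning) is the standard way to keep
the comparison defined.  On rotation classes this is a pseudometric;
the tests spot-check symmetry and the triangle inequality on random
orders.

## Skews

AT skew = (A−T)/(A+T), GC skew = (G−C)/(G+C), with `NA` (not an
error) on a zero denominator; ambiguity codes are excluded from all
denominators.  Sign conventions follow the majority strand — the
strand encoding most genes.  A strand tie is an error rather than a
silent pick, because a wrong majority strand flips every downstream
sign.

`skew_profile()` reports four resolutions:

* whole genome, read on the majority strand;
* per gene, in each gene's own coding orientation — so the statement
  "all majority-strand genes have negative GC skew" is directly
  assertable on the profile;
* per strand class: concatenated protein-coding genes of each strand,
  in coding orientation.  Reporting the minority class in
  minority-strand orientation (rather than re-complemented) was an
  open convention; coding orientation was chosen and is documented
  here because it matches how per-gene skews are plotted in
  comparative work, where the two strand classes appear with opposite
  signs;
* per codon position (1/2/3) of the two concatenated classes,
  complete codons only.  Genes whose span is not divisible by three
  (truncated stop codons such as a bare `T`) drop their trailing
  partial codon with a warning.  Complete stop codons are included:
  the simpler contract, logged here because the convention is not
  standardized.

`classify_skew_pattern()` maps a skew pair to `CRUSTACEAN_TYPE`
(AT > ε, GC < −ε), `INVERTED_TYPE` (AT < −ε, GC > ε) or
`INDETERMINATE`.  The literature classifies by sign only; the dead
zone ε (default 0.05, dimensionless, configurable) exists to keep
short or nearly-balanced sequences from flipping class on sampling
noise.  ε = 0 recovers the pure sign rule.

## NCR tRNA-fragment scan

Incomplete tRNA sets are common in isopods, and degenerate central
segments of missing tRNAs can persist in non-coding regions.  The
detector implements the minimal canonical anticodon-arm geometry: a
7-nt loop with the anticodon at loop positions 3–5, closed by at
least `min_stem` (default 3) contiguous Watson–Crick or GU-wobble
pairs, scanned on both strands of every NCR longer than `min_ncr`
(default 10 bp) expanded by `flank` (default 20 bp, the upper end of
the window sizes used when re-checking NCRs against neighbouring
genes) into its neighbours.  The score is the stem length and nothing
else — no thermodynamics — so every hit is exactly explainable and
the plant-and-recover tests can assert exact offsets.  `min_stem = 3`
is a declared default, not a published acceptance threshold; there is
no community criterion for calling a fragment "conserved".  The scan
deliberately does not attempt full cloverleaf folding or
post-transcriptional-editing models.

## Synthetic mitogenomes

`simulate_mitogenome()` reuses a real architecture template verbatim
(by default the shipped 14.4-kb isopod table: 13 PCGs, 2 rRNAs,
19 tRNAs, one control region, 14 overlaps) and draws fresh sequence:
each gene from the composition implied by its strand class — and for
protein-coding genes, per-codon-position targets — written in the
gene's orientation; uncovered positions from a skewless background.
A base composition is parameterized by AT fraction `f` and the two
skews: `p_A = f(1+s_AT)/2`, etc.  Defaults are the published values
for the template genome where available (AT fraction 0.681;
majority-strand AT/GC skew targets 0.111/−0.423; majority GC by codon
position −0.122/−0.20/−0.769 with the second position interpolated;
minority GC by codon 0.547/0.323/0.825), with the remaining minority
AT targets set to plausible moderate values of the opposite sign.
Where features overlap, the later feature wins; overlaps are ≤ 9 bp
here, so the distortion of realized per-gene skews is negligible
relative to binomial noise.  Realized skews converge to targets at
rate `3σ ≈ 3·sqrt((1−s²)/n)` on the relevant base count, which the
tests assert at two lengths.

The template's truncated-stop genes make some PCG spans indivisible
by three; the generator cycles codon phase and allows a final partial
codon rather than rejecting real architectures.

What this generator does **not** emulate: codon structure that
translates (amino-acid plausibility is not enforced), site-rate
heterogeneity, within-gene skew gradients, and any replication
mechanism — it produces compositional stand-ins, so a green
simulator-recovery test establishes that the skew accounting is
self-consistent, not that real mitogenomes evolve this way.

## The alignment simulator and the LBA experiment

Sequences evolve along a known rooted tree under a
composition-biased replacement model: on a branch of expected length
`b` (substitutions/site), each site is hit with probability
`1 − exp(−b)` and redrawn from the base-frequency vector π of the
child lineage's composition group (internal lineages inherit their
parent's group unless overridden).  This is the minimal exactly
simulable model that produces compositional attraction; it was chosen
over a non-stationary GTR deliberately, to keep the experiment
interpretable.  Two useful closed forms follow: the per-branch kernel
`M = e^{−b}I + (1−e^{−b})𝟙π'` has `det M = e^{−3b}`, so the
paralinear (LogDet) length of a path is 0.75·Σb plus an
end-composition term — the tests use this as an independent oracle
for the LogDet estimator; and a leaf's composition converges to its
group's π at rate `e^{−b}`.

The experiment's default world: 12 ingroup taxa; two homoplastic
*pairs* (`c1,c2` and `a1,a2`), deliberately not sisters, each on a
stem branch of 0.7 along which the composition switches to a shared
GC-rich state (0.15, 0.35, 0.35, 0.15), everything else at the
AT-rich mirror composition.  Pairs — not single taxa — because that
is the structure of the real phenomenon (families of
double-inverted-skew species, a pair of Asellota), and because a
convergent *lineage* is internally tight, which gives an attracted
outgroup an attachment point outside it.  Outgroup strategies: none;
a single outgroup on a long branch (1.5) *sharing the homoplastic
composition* (modelling an outgroup whose skew state matches the
convergent ingroup taxa); or five background-composition outgroups.

The artefact is scored as: some edge of the neighbor-joining tree
separates the four homoplastic taxa — possibly together with
homoplastic-composition outgroups — from everything else
(`homoplastic_cluster_test()`).  Making like-composed outgroups
"transparent" is a considered choice: compositional attraction
routinely pulls such an outgroup *into the middle* of the artefactual
cluster, and scoring that outcome as "no artefact" would invert the
measurement.  The stem length 0.7 was chosen, after surveying the
design space during development, as the regime that reproduces the
qualitative published pattern rather than a saturated one: without an
outgroup the artefact occurs but is not certain; a single
like-composed outgroup drives it to near-certainty; many outgroups
suppress it; LogDet suppresses it everywhere.  The directional
contracts asserted by the acceptance tests (p-distance ≥ LogDet per
strategy with a positive mean margin; single ≥ none under p-distance,
with a margin) hold across the surveyed 0.6–0.8 range; magnitudes are
reported, never asserted.

Two caveats the experiment makes explicit rather than hiding.  First,
with zero compositional shift the p-distance cells do *not* go to
zero while long branches remain — p-distances are non-additive under
saturation, so classical branch-length LBA persists; only removing
both signals silences every cell (the tests assert exactly that).
Second, the experiment is a desk-scale analogue: it demonstrates the
*mechanism* (compositional homoplasy misleading composition-blind
distances, modulated by outgroup choice) at nucleotide level with
neighbor joining, not a reproduction of any published
amino-acid/CAT-GTR topology.

## Numerical and determinism choices

* Neighbor joining: standard Q-criterion agglomeration; ties broken
  by the lexicographically smallest pair of cluster representatives
  (smallest leaf label per cluster), so taxon order cannot change the
  result; negative branch-length estimates clamped to zero and
  flagged.  Exact on additive matrices, which the tests verify
  against a brute-force least-squares topology search.
* LogDet: `d = −(1/4)(log det F − (1/2)Σ log r_i c_i)` on the joint
  frequency table; singular tables yield `NA` plus a `saturated`
  flag instead of an error.  Negative estimates (possible on
  near-identical pairs by rounding) are clamped to zero.
* Robinson–Foulds and clade tests run on explicit bipartition sets
  from one postorder pass; they are cross-checked against independent
  enumeration oracles in the tests.
* Every generator requires an explicit seed; experiment replicate `r`
  of strategy `s` derives seed `seed + 1000·s + r`, and all stochastic
  assertions are pinned to fixed seeds and replicate counts.
* A replicate whose LogDet matrix contains a saturated pair is
  counted as a non-artefact for that method (the denominator stays at
  the replicate count) and tallied in the result's `saturated`
  attribute; at the default 2-kb length saturation does not occur.

## Known limitations

* The GenBank reader is a minimal offline single-record parser
  (LOCUS/ORGANISM, the common feature keys, `complement`, two-segment
  origin-spanning `join`); it is not a general GenBank library.
* Sequence-level published values for the shipped annotation (overall
  A+T content, whole-genome skews) cannot be recomputed because no
  public sequence accompanies the printed table; they are covered by
  simulator-recovery and property tests instead, with the published
  values used as simulator targets.
* No rearrangement-scenario reconstruction (inversion/TDRL histories)
  and no Bayesian or mixture-model phylogenetics; the distance
  methods here are the mechanistic counterfactual, not a
  reimplementation of the published pipelines.
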