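---
title: "Methods: domain structure and concerted evolution of alpha-satellite HOR arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain structure and concerted evolution of alpha-satellite HOR arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The biological problem

Human centromeres sit on alpha-satellite DNA: tandem arrays of ~171-bp
monomers. In the homogeneous arrays where CENP-A nucleosomes assemble, the
monomers are organised into higher-order repeats (HORs) — multimers of k
diverged monomers that are themselves tandemly repeated at very high
(>97%) identity. These arrays evolve concertedly, and the informative signal
for reconstructing *how* is the pattern of rare variant positions:

- A **Diagnostic Variant Nucleotide (DVN)** is a variant state at a consensus
  position shared by at least two repeat copies of the analysed set. Shared
  variation must have spread between copies (by unequal crossover or
  conversion) or have been co-inherited from a duplication; it is diagnostic
  of exchange history.
- A **sporadic mutation** is a singleton — plain mutational noise that has
  not (yet) spread.

Blocks of array-ordered copies sharing DVN combinations (haplotypes) are
**homogenisation domains**: the footprint of accumulated unequal crossovers,
which homogenise and expand a neighbourhood of the array. Short runs of
copies dissimilar to both flanking domains act as **barriers** that stop
further exchange between them; adjacent near-identical copies with
pair-private DVNs mark recent **duplications by unequal crossover**; runs of
one domain's DVNs inside a copy of another domain mark **gene-conversion
tracts**, which — counter to the classical intuition — inject divergence
into an otherwise homogeneous neighbourhood.

`alphadom` implements the full chain from raw array sequence to these event
calls, plus a forward-time simulator of the underlying evolutionary model so
that every stage can be scored against planted ground truth.

# Pipeline stages and their assumptions

## Monomer decomposition

`detect_monomers()` tiles the array greedily left to right with semi-global
alignments of a monomer consensus (match +1, mismatch −1, gap open 4, gap
extend 1), accepting calls at ≥ 60% identity within ±15 bp of the expected
next start. Calls plus unassigned gaps exactly partition the array. The 60%
floor is deliberately permissive: monomers of divergent flanking alphoid DNA
still tile (so HOR phasing stays in register across the whole array) while
non-alphoid sequence does not.

When no consensus is supplied, `derive_monomer_consensus()` finds the
monomer period by maximising the autocorrelation of exact 8-mer matches
over lags 150–200 bp, then *re-tiles* the array with a seed window of that
length and majority-votes the called instances. Re-tiling, rather than
chopping the array at the fixed lag, matters because real monomers vary by a
few bases in length (169–171 bp) and fixed-lag chopping lets the phase
drift through the array, smearing the consensus. The rotation of a
self-derived monomer consensus is intrinsically arbitrary; it is
canonicalised to the first monomer boundary of the array so that repeated
runs are identical. Unit numbering downstream is therefore reproducible up
to a fixed rotation of the HOR phase, which is also the best any assembly
with unannotated phase can offer.

## HOR period and phasing

`infer_hor_period()` scores each candidate period k by the mean identity of
monomer pairs at lag k. Because any multiple of the true period scores
(nearly) as well as the period itself, the bare argmax is unstable; the
period is the *smallest* lag within a contrast-scaled band
(min(0.05, (max − median)/3)) of the maximum. A profile whose maximum is
within 0.02 of its median is declared structureless — an array of identical
monomers has period 1 and no higher-order signal.

`phase_hors()` cuts units every k monomers. Restriction-site anchoring
(HindIII = `AAGCTT`; the standard recognition sequence, since the enzyme
defines the classical 1.9-kb ladder of this locus family) places unit starts
at the monomer containing the site's first base, taking the modal phase over
all site-bearing monomers and refusing to anchor when fewer than half of the
candidate units contain the site. Max-homogeneity anchoring maximises mean
adjacent-unit identity; note that for a perfectly tandem array every offset
is equally homogeneous, so this anchor is only informative when edges or
flanks break the symmetry — the restriction site is the physically
meaningful anchor.

`extract_core()` keeps the longest contiguous run of complete units within
5% divergence of the unit consensus, mirroring the observed architecture:
homogeneous centre, divergent sides. At the observed variation level a core
copy carries roughly 70 variant positions out of 1866 (~3.8% divergence),
comfortably inside the filter, while 10%-divergent flanking units are
comfortably outside; the default is central between those regimes.

## Consensus anchoring and variant calling

All near-identical copies are aligned *to the consensus*, not to each other
(`anchor_align()`): each copy is globally aligned to the consensus with the
scoring above and projected onto consensus columns; copy bases opposite
consensus gaps are kept as insertion records rather than new columns. This
keeps one fixed coordinate system — the property every downstream statistic
relies on — at the cost of not representing insertions as columns.
Insertions are therefore reported but excluded from DVN statistics;
deletions (`-`) are ordinary DVN-eligible states. The consensus is
re-estimated once from the projected matrix and copies realigned if it
changed; with copies at >96% identity one round always converges.

`classify_dvns()` groups variants by (column, alternative state); groups
with ≥ 2 carriers are DVNs, the rest sporadic. The headline count is
`dvn_columns`, the number of *positions* bearing at least one DVN group,
because a position can carry two alternative shared states and printed
position counts are the field's convention. The sporadic rate is
100 × singletons / (copies × columns); per-copy rates are also emitted
because an "average" rate is ambiguous between the two denominators.

The CENP-B box scan scores each monomer's best window against the 17-bp
degenerate consensus `NTTCGNNNNANNCGGGN` at its nine non-N positions, which
are the ones essential for CENP-B binding; a box is intact only at 9/9.

## Domain segmentation and event inference

Copies are represented by binary DVN-carrier vectors (haplotypes). Jaccard
similarity is used throughout: copies with no DVNs at all — which occur in
real clone sets — then have similarity 0 to everything and are left
unassigned rather than forced into a domain. `segment_domains()` merges
adjacent segments agglomeratively while the best adjacent-pair mean Jaccard
is ≥ τ = 0.2; final segments of ≥ 2 copies become domains whose defining
DVN set is the groups carried by ≥ 50% of members. τ = 0.2 sits between
within-domain similarity (≈ 0.4–0.7 at observed carrier frequencies) and
cross-domain similarity (≈ 0) and recovers planted boundaries exactly in
≥ 90% of seeded replicates (the property suite measures this).

`detect_barriers()` flags runs between two domains whose mean Jaccard to
*both* flanks is < β = 0.05 — including small interior domains, since a
duplicated divergent block is precisely how a barrier arises.
`detect_duplicate_pairs()` reports adjacent copies at ≥ 99.5% row identity
with the DVN groups private to exactly that pair. `detect_conversion_tracts()`
scans, for each copy of domain D and each other domain D′, the ordered
defining columns of D ∪ D′: a maximal run of ≥ k_min = 3 consecutive
D′-defining columns carried by the copy, uninterrupted by any carried
D-defining state, is one tract with donor D′. Positions defining neither
domain are neutral — a conversion tract replaces the acceptor's sequence
wholesale, so interior columns where the copy simply lacks a defining state
must not break the run.

## Set comparison and intermingling

For unordered clone sets (PCR clones have unknown array positions),
segmentation is meaningless and comparison is clustering-based:
`compare_sets()` aligns both sets to one joint consensus, recomputes DVNs,
classifies each group as shared or private by carrier provenance, and emits
an average-linkage tree on haplotype Hamming distance.

The intermingling statistic formalises "how mixed are two sets in DVN
space": the fraction of repeats whose nearest non-self neighbour belongs to
the other set, with ties contributing fractionally (deterministic, no
arbitrary ordering). It is normalised by its expectation under random
labels — for a member of A, |B|/(|A|+|B|−1) — so fully mixed sets score ~1
and fully separated sets 0; significance comes from a seeded label
permutation test (upper tail: more intermingled than random). The statistic
is our formalisation of a qualitative clustering observation, and is
flagged as such.

# The forward-time simulator

`evolve()` advances an array one generation at a time with a fixed event
order (mutation → conversion → crossover), which makes the event log
deterministic and replayable bit-for-bit (`replay_log()` — the correctness
contract of the logger, and the anchor for every recovery test).

Per generation:

1. **Mutation** — Poisson(μ × unit length) substitutions per copy, uniform
   positions, uniform different base.
2. **Conversion** — Poisson(conv_rate) events; uniform acceptor, donor
   uniform within ± xo_offset_max copies, geometric tract (mean
   conv_tract_mean bp) overwritten from the donor. Copy-number neutral.
3. **Unequal crossover** — Poisson(xo_rate) attempts between copy i and
   copy i+d (d ≤ xo_offset_max); an attempt succeeds only if the two
   full units are ≥ xo_identity_min identical (the similarity gate
   operationalising "exchange only between close, near-identical repeats"
   with a single number, measured on the whole unit). A fair coin keeps the
   expansion or the contraction product — single-chromatid bookkeeping,
   since one chromosome lineage is followed. Events that would leave
   `copy_bounds` are rejected and logged as such.

Defaults (55 copies × 1866 bp, μ = 2·10⁻⁵/bp/copy/generation over 100
generations, i.e. ~0.2% accumulated sporadic divergence; conv_rate 0.5;
xo_rate 0.2 gated at 98% identity within ±5 copies) are calibrated only to
the qualitative regimes the analysis targets — 0.2–0.5% sporadic divergence
bands, crossover-driven homogenisation, conversion-driven diversification —
not fitted to any dataset. Indels are not simulated by default: the
diagnostic variation in these arrays is overwhelmingly substitutions plus
rare deletions, and alignment stress-tests plant deletions directly.

## Planted-truth generators

The forward simulator produces realistic *histories*; recovery tests need
known *answers*. `plant_domain_array()` builds arrays with exact planted
structure: disjoint per-domain DVN column sets, each carried by a domain
member with probability `carrier_frac` (≥ 2 carriers — the DVN definition —
and capped at 42% of all copies so the ancestral state keeps an absolute
consensus majority even after conversion recipients are added on top);
sporadic mutations planted as true singletons at distinct free columns.
`plant_conversion()` overwrites a run of donor-domain DVN columns in a
recipient copy, wiping the recipient's own states inside the tract, exactly
as a conversion event would.

`sim_archetype_array()` assembles the full published architecture in one
record: a 141,084-bp array whose central 55 × 1866-bp units (11 monomer
families ~15% diverged from a base monomer; lengths 169/170 bp summing to
1866) carry 281 DVN positions split into domains 1–30 / 31–35 / 36–55 with
the near-identical pair 32/33 (16 pair-private DVNs, ≤ 2 sporadics each so
the pair stays ≥ 99.5% identical, as a fresh duplicate would), 205 sporadic
singletons (0.2% of cells), one HindIII site and one CENP-B box per unit,
and 10%-divergent flanking units padding both sides. Deletion-type DVNs are
planted rarely (3 columns × 3 carriers) at columns whose neighbours differ
from them, so the unit length stays modal at 1866 bp and gap placement in
pairwise alignment is unambiguous; DVN and sporadic planting avoids the
site, the box and 8 bp at each unit edge, so restriction anchoring and unit
boundaries stay exact. The structural constants are study conditions, not
tunables; the seed only moves random sequence content around them.

# What the synthetic data does and does not show

The generators emulate: tandem HOR structure with realistic monomer-family
divergence and length variation; DVN densities matching the archetype
(~0.05–0.06 defining columns per bp per domain — the recovery suites for
conversion tracts use this density so a 5-DVN tract spans a realistic
fraction of the unit); sporadic noise at the observed 0.2–0.5% band;
PCR-clone sampling with window truncation, anonymous ids and duplicate
clones.

They do not emulate: retrotransposon interruptions or non-alphoid inserts;
strand ambiguity (inputs are used in the given orientation); sequencing
error; insertions at meaningful rates; selection or meiotic drive. Passing
the recovery suites therefore shows that the statistics are implemented
correctly and are well-calibrated at realistic signal strengths — not that
real arrays satisfy the model's assumptions. On real data the alignment
stage also inherits whatever assembly errors the input carries.

# Numerical choices and conventions

- **Coordinates** are 1-based closed intervals throughout, the
  Bioconductor/IRanges convention.
- **Consensus ties** are broken by the fixed order A < C < G < T < `-`;
  `N` never wins a column. Copies containing `N` are excluded from variant
  calling but stay flagged, never silently dropped.
- **Alignment scoring** (match +1, mismatch −1, gap open 4, gap extend 1) is
  exposed config; published figures from other aligners are regenerated,
  not byte-matched, since their parameters are unstated.
- **Restriction fragments** are cut-to-cut (start-to-start) distances plus
  flanks; non-palindromic sites are scanned on both strands.
- **Degenerate inputs**: empty alignments, zero-DVN sets, single-domain
  maps and empty barrier lists are returned as flagged empty results, not
  errors; genuinely undefined quantities (sporadic rate of an empty
  alignment, intermingling of an empty set) raise typed errors.
- **Determinism**: every stochastic function takes or derives a seed;
  pipeline result files contain no timestamps (those live in `run.log`), so
  identical configurations reproduce byte-identical outputs.

# Problem sizes

The bundled test and acceptance runs use: the full 141-kb archetype once
per session (~1 minute through the whole pipeline); 200 random ≤ 8 × 60
alignments against a brute-force oracle; 50 mutation-recovery replicates at
each of 0.2% and 0.5% planted divergence (20 copies × 652 bp — the clone
window of the homologue analyses); 100 planted-domain and 100
conversion-tract replicates (20+20 copies × 400 bp); 20 replay
parameterisations; and 20 replicates × 10 time points for the
lineage-divergence trend (15 copies × 250 bp). These sizes give stable
means for every reported statistic while keeping a full run in a few
minutes on one core.

# Known limitations

- Max-homogeneity phasing is degenerate on perfectly tandem arrays (every
  offset ties); use restriction-site anchoring when a site is available.
- The consensus-anchored aligner assumes copies within 20% of consensus
  length; grossly rearranged units should be split upstream.
- Conversion tracts are only detectable between domains with disjoint
  defining states and at ≥ k_min consecutive donor columns; short tracts
  and tracts between similar domains are invisible in principle, not just
  in this implementation.
- The intermingling index compares exactly two sets; multi-set comparisons
  are run pairwise.
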