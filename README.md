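# alphadom

Domain structure and concerted evolution of alpha-satellite higher-order
repeat (HOR) arrays.

Human centromeres form on alpha-satellite DNA: tandem arrays of ~171-bp
monomers organised, in the homogeneous arrays that recruit CENP-A, into
higher-order repeats — k-monomer units (here k = 11, 1866 bp) repeated in
tandem at >97% identity. These arrays evolve concertedly through unequal
crossovers that homogenise and expand neighbourhoods of the array, gene
conversions that paradoxically inject divergence, and sporadic mutations.
`alphadom` is for molecular evolution and centromere researchers who want to
reconstruct that history from sequence alone.

The informative signal is the set of **Diagnostic Variant Nucleotides
(DVNs)**: variant states at consensus positions shared by ≥ 2 repeat copies.
For an alignment of n copies over L consensus columns, each copy c gets a
binary haplotype h_c over DVN groups; array-ordered copies are segmented
into **homogenisation domains** by adjacency-constrained agglomerative
merging on mean inter-segment Jaccard similarity J(h_i, h_j) (stop at
τ = 0.2); runs with J < β = 0.05 to both flanking domains are **barriers**;
adjacent copies at ≥ 99.5% identity with pair-private DVNs are
**unequal-crossover duplicates**; runs of ≥ 3 consecutive donor-domain DVN
columns inside a copy of another domain are **conversion tracts**. The
singleton fraction 100·|sporadic|/(n·L) is the **sporadic mutation rate**.
Two repeat sets (homologues, or CENP-A-associated vs bulk) are compared on a
joint alignment by DVN provenance (shared vs private), a co-clustering tree,
and a nearest-neighbour **intermingling index** — the tie-averaged fraction
of repeats whose nearest neighbour in haplotype Hamming distance lies in the
other set, normalised by its random-label expectation 2|A||B|/(n(n−1)) and
tested by label permutation.

A forward-time simulator implements the evolutionary model itself —
per-generation Poisson substitutions, geometric-tract gene conversion, and
unequal crossover gated to near-identical partners within ± 5 copies, with a
bit-exact replayable event log — so every pipeline stage is tested against
planted ground truth, with no external data.

## Worked example

Plant a two-domain array (20 + 20 copies of a 400-bp unit, 12 DVN columns
per domain, 0.2% sporadic noise), call variants, and segment it:

```r
library(alphadom)

pl   <- plant_domain_array(n_copies = c(20, 20), unit_len = 400,
                           n_dvns = c(12, 12), seed = 42)
aln  <- alignment_from_copies(pl$copies)
part <- classify_dvns(call_variants(aln), n_copies = 40)
part
#> <variant_partition> 24 DVN group(s) at 24 position(s); 32 sporadic mutation(s); 40 copies

sporadic_rate(part, aln)$rate_pct
#> [1] 0.2

hm  <- haplotype_matrix(part, names(pl$copies))
map <- detect_barriers(segment_domains(hm), hm)
map
#> <domain_map> 2 domain(s), 0 barrier(s), 0 unassigned copy(ies) over 40 copies
#>   domain 1: copies 1-20 (12 defining DVNs)
#>   domain 2: copies 21-40 (12 defining DVNs)
```

All 24 planted DVN columns are recovered as shared variants, the 32
singletons land at the planted 0.2% rate, and segmentation splits the array
exactly at the planted boundary — each domain defined by its own 12 DVNs.

For raw sequence input the same chain starts from decomposition:
`detect_monomers()` → `infer_hor_period()` → `phase_hors()` →
`extract_core()` → `anchor_align()`, or in one call via `run_pipeline()`
with a YAML/list configuration.

## The analysis workflow

Numbered drivers under `analysis/` rebuild the package's full study on
synthetic data and write their tables under `results/`:

1. `01_simulate.R` — generate the 141,084-bp archetype array (55 × 1866-bp
   homogeneous core, 281 planted DVN positions, divergent flanks) and
   homologue clone sets from a split-lineage simulation.
2. `02_decompose.R` — self-derive the monomer consensus, infer k = 11,
   phase at the HindIII site, digest in silico (modal fragment 1866 bp ≈
   1.9 kb), extract the 55-unit core.
3. `03_variants.R` — consensus-anchored alignment, 281 DVN positions vs
   ~0.2% sporadic cells, CENP-B box scan.
4. `04_segment_events.R` — domains 1–30 / 31–35 / 36–55, the 31–35 barrier,
   duplicate pair (32, 33) at 99.8% identity with 16 pair-private DVNs,
   conversion-tract scan.
5. `05_compare.R` — homologue clone-set comparison (shared vs private DVNs,
   tree, intermingling calibration).

Run them in order from the repository root:
`Rscript analysis/01_simulate.R`, etc. Bulky intermediate sequence data
goes under `scratch/`.

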