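#!/usr/bin/env Rscript
## 03 — Consensus-anchored alignment, DVN calling, CENP-B box scan.
##
## Aligns the 55 core units onto one consensus coordinate system, partitions
## per-copy variants into DVNs (shared by >= 2 copies) versus sporadic
## singletons, and scans each monomer of the first unit for the CENP-B box.
## Finding: 281 of the 1866 consensus positions carry DVNs, while sporadic
## mutations sit at ~0.2% of aligned cells — diagnostic variation dominates
## random noise by an order of magnitude.

library(alphadom)
dir.create("results", showWarnings = FALSE)

arch <- sim_archetype_array(seed = 101)
mono <- detect_monomers(arch$record, monomer_consensus = arch$monomer_consensus)
period <- infer_hor_period(mono)
phasing <- phase_hors(mono, period$k, anchor = "restriction_site", site = "AAGCTT")
core <- extract_core(phasing)

aln <- anchor_align(core$unit_seqs)
part <- classify_dvns(call_variants(aln), n_copies = nrow(aln$mat))
rate <- sporadic_rate(part, aln)
cat(sprintf("alignment: %d copies x %d columns\n", nrow(aln$mat), ncol(aln$mat)))
cat(sprintf("DVNs: %d groups at %d positions; %d sporadic singletons (%.3f%% of cells)\n",
            nrow(part$dvns), part$dvn_columns, nrow(part$sporadic), rate$rate_pct))

# CENP-B boxes along the monomers of the first core unit
u1 <- core$units[1, ]
monomer_seqs <- substring(mono$array_seq,
                          mono$calls$start[u1$first_monomer:u1$last_monomer],
                          mono$calls$end[u1$first_monomer:u1$last_monomer])
boxes <- scan_cenpb(monomer_seqs)
cat(sprintf("CENP-B boxes in unit 1: %d/%d monomers with a box, %d intact (9/9 essential)\n",
            sum(boxes$present), nrow(boxes), sum(boxes$intact)))

dvn_table <- part$dvns[, c("column", "alt_state", "n_carriers")]
write_report(dvn_table, "results/03_dvns.tsv")
write_report(boxes, "results/03_cenpb_boxes.tsv")
write_report(list(
  n_copies = nrow(aln$mat), n_columns = ncol(aln$mat),
  dvn_groups = nrow(part$dvns), dvn_positions = part$dvn_columns,
  sporadic = nrow(part$sporadic), sporadic_rate_pct = rate$rate_pct,
  per_copy_sporadic_pct = as.list(round(rate$per_copy_pct, 4))
), "results/03_variants_summary.json", format = "json")
cat("wrote results/03_dvns.tsv, results/03_cenpb_boxes.tsv, results/03_variants_summary.json\n")
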