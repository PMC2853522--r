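#!/usr/bin/env Rscript
## 01 — Generate the study inputs in code.
##
## Builds (a) the synthetic archetype array: a 141,084-bp alphoid record with
## a homogeneous core of 55 x 1866-bp HOR units (k = 11), 281 planted DVN
## positions in domains 1-30 / 31-35 / 36-55, the near-identical pair 32/33,
## ~0.2% sporadic singletons and divergent flanks; and (b) a pair of
## homologue-like clone sets from a split-lineage forward simulation.
## Sequence data goes under scratch/ (bulky); small summaries under results/.

library(alphadom)

dir.create("scratch/analysis", recursive = TRUE, showWarnings = FALSE)
dir.create("results", recursive = TRUE, showWarnings = FALSE)

arch <- sim_archetype_array(seed = 101)
save_sequences(arch$record, "scratch/analysis/archetype.fa")
cat(sprintf("archetype array: %d bp, %d planted DVN positions, %d sporadic singletons\n",
            nchar(arch$record$sequence), arch$n_dvn_columns, nrow(arch$sporadic)))

# two homologue lineages: shared history, then independent evolution
p <- sim_params(n0 = 30, unit_len = 652, mu = 2e-5, conv_rate = 0.4,
                conv_tract_mean = 120, xo_rate = 0.8, xo_identity_min = 0.95,
                xo_offset_max = 4, generations = 150, seed = 202)
master <- evolve(init_array(p), p)$array
lineages <- split_lineages(master, p, g_split = 150)
clones_a <- sample_clones(lineages$a, n = 25, dup_prob = 0.1, seed = 301)
clones_b <- sample_clones(lineages$b, n = 25, dup_prob = 0.1, seed = 302)
save_sequences(clones_a, "scratch/analysis/clones_homologue_A.fa")
save_sequences(clones_b, "scratch/analysis/clones_homologue_B.fa")
cat(sprintf("homologue clone sets: %d + %d anonymous clones of %d bp\n",
            nrow(clones_a), nrow(clones_b), nchar(clones_a$sequence[1])))

write_report(list(
  archetype = list(length_bp = nchar(arch$record$sequence),
                   planted_dvn_positions = arch$n_dvn_columns,
                   planted_sporadic = nrow(arch$sporadic),
                   core_units = arch$n_core, hor_period = arch$k,
                   unit_length_bp = arch$unit_len),
  homologue_simulation = list(copies_per_lineage_end =
                                c(length(lineages$a$copies),
                                  length(lineages$b$copies)),
                              clones_per_set = 25,
                              split_generations = 150)
), "results/01_simulation.json", format = "json")
cat("wrote results/01_simulation.json\n")
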