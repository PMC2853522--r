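make_partition <- function(rows) {
  aln <- aln_from_rows(rows)
  classify_dvns(call_variants(aln), n_copies = length(rows))
}

test_that("the haplotype matrix records DVN carriage in array order", {
  # 2 DVNs with carriers {1,2} and {2,3}; copy 4 carries nothing
  part <- make_partition(c("TAAA", "TCAA", "ACAA", "AAAA", "AAAA"))
  hm <- haplotype_matrix(part, sprintf("copy_%02d", 1:5))
  expect_equal(unname(hm$mat[1:3, ]),
               matrix(c(1L, 0L, 1L, 1L, 0L, 1L), nrow = 3, byrow = TRUE))
  expect_equal(unname(rowSums(hm$mat)[4:5]), c(0, 0))
  # zero DVN groups is a flagged empty matrix, not an error
  none <- make_partition(c("AAAA", "AAAA", "AAAA"))
  hm0 <- haplotype_matrix(none, sprintf("copy_%02d", 1:3))
  expect_true(hm0$empty)
  expect_equal(ncol(hm0$mat), 0L)
})

test_that("identical haplotypes collapse to a single domain", {
  # six copies sharing one identical non-empty haplotype (carrier pattern
  # fixed by a wider reference set)
  mat <- matrix(rep(c(1L, 0L, 1L), each = 6), nrow = 6,
                dimnames = list(sprintf("copy_%02d", 1:6),
                                c("c10T", "c20C", "c31-")))
  hm <- structure(list(mat = mat,
                       dvn_meta = data.frame(column = c(10L, 20L, 31L),
                                             alt_state = c("T", "C", "-"),
                                             n_carriers = c(6L, 0L, 6L)),
                       empty = FALSE), class = "haplotype_matrix")
  map <- segment_domains(hm)
  expect_equal(nrow(map$domains), 1L)
  expect_equal(c(map$domains$first_copy, map$domains$last_copy), c(1L, 6L))

  # all-zero haplotypes have similarity 0 to everything: nothing merges
  hm0 <- hm
  hm0$mat[] <- 0L
  map0 <- segment_domains(hm0)
  expect_equal(nrow(map0$domains), 0L)
  expect_equal(map0$unassigned, 1:6)
})

test_that("planted two-domain arrays segment at the planted boundary", {
  pl <- plant_domain_array(seed = 61)
  aln <- alignment_from_copies(pl$copies)
  part <- classify_dvns(call_variants(aln), n_copies = length(pl$copies))
  hm <- haplotype_matrix(part, names(pl$copies))
  map <- segment_domains(hm)
  expect_equal(map$domains$first_copy, c(1L, 21L))
  expect_equal(map$domains$last_copy, c(20L, 40L))

  # block structure matches planted membership
  block <- hm$mat[, paste0("c", pl$dvns$column, pl$dvns$alt_state)]
  dom1_cols <- pl$dvns$domain == 1
  expect_gt(mean(block[1:20, dom1_cols]), 0.5)
  expect_equal(sum(block[1:20, !dom1_cols]), 0)
})

test_that("segmentation mirrors under reversal of array order", {
  pl <- plant_domain_array(n_copies = c(12L, 18L), seed = 62)
  aln <- alignment_from_copies(pl$copies)
  part <- classify_dvns(call_variants(aln), n_copies = length(pl$copies))
  hm <- haplotype_matrix(part, names(pl$copies))
  map <- segment_domains(hm)
  hm_rev <- hm
  hm_rev$mat <- hm$mat[rev(seq_len(nrow(hm$mat))), , drop = FALSE]
  map_rev <- segment_domains(hm_rev)
  n <- nrow(hm$mat)
  expect_equal(sort(n + 1L - map_rev$domains$last_copy), sort(map$domains$first_copy))
  expect_equal(sort(n + 1L - map_rev$domains$first_copy), sort(map$domains$last_copy))
})

test_that("a divergent spacer between domains is called as a barrier", {
  # three planted blocks; the tiny middle one is dissimilar to both sides
  pl <- plant_domain_array(n_copies = c(15L, 4L, 15L),
                           n_dvns = c(12L, 8L, 12L), seed = 63)
  aln <- alignment_from_copies(pl$copies)
  part <- classify_dvns(call_variants(aln), n_copies = length(pl$copies))
  hm <- haplotype_matrix(part, names(pl$copies))
  map <- detect_barriers(segment_domains(hm), hm)
  expect_equal(nrow(map$barriers), 1L)
  expect_equal(c(map$barriers$first_copy, map$barriers$last_copy), c(16L, 19L))
  expect_lt(map$barriers$flank_cross_sim, 0.05)

  # two directly adjacent domains: no barrier
  pl2 <- plant_domain_array(seed = 64)
  aln2 <- alignment_from_copies(pl2$copies)
  part2 <- classify_dvns(call_variants(aln2), n_copies = length(pl2$copies))
  hm2 <- haplotype_matrix(part2, names(pl2$copies))
  map2 <- detect_barriers(segment_domains(hm2), hm2)
  expect_equal(nrow(map2$barriers), 0L)
})

test_that("adjacent near-identical copies are reported as duplicate pairs", {
  pl <- plant_domain_array(seed = 65)
  copies <- pl$copies
  copies[21] <- copies[22]   # plant an unequal-crossover duplication
  aln <- alignment_from_copies(copies)
  part <- classify_dvns(call_variants(aln), n_copies = length(copies))
  pairs <- detect_duplicate_pairs(aln, part)
  hit <- pairs$copy_i == 21L & pairs$copy_j == 22L
  expect_true(any(hit))
  expect_equal(pairs$identity[hit], 1)

  # mutually ~95%-identical copies yield nothing
  withr::with_seed(66, {
    anc <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                 collapse = "")
    rows <- vapply(1:6, function(i) alphadom:::mutate_fixed(anc, 10),
                   character(1))
  })
  aln2 <- alignment_from_copies(setNames(rows, paste0("c", 1:6)))
  expect_equal(nrow(detect_duplicate_pairs(aln2)), 0L)
})

test_that("conversion tracts are detected at and only above the run threshold", {
  pl <- plant_domain_array(seed = 67)
  pl <- plant_conversion(pl, n_tracts = 1L, tract_dvns = 5L, seed = 68)
  aln <- alignment_from_copies(pl$copies)
  part <- classify_dvns(call_variants(aln), n_copies = length(pl$copies))
  hm <- haplotype_matrix(part, names(pl$copies))
  map <- segment_domains(hm)
  tr <- detect_conversion_tracts(hm, map)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$copy_index, pl$tracts$copy)
  expect_equal(tr$donor, 2L)
  expect_equal(tr$n_dvns, 5L)
  expect_equal(tr$col_start, pl$tracts$col_start)
  expect_equal(tr$col_end, pl$tracts$col_end)

  # a run of k_min - 1 is not reported
  pl2 <- plant_domain_array(seed = 69)
  pl2 <- plant_conversion(pl2, n_tracts = 1L, tract_dvns = 2L, seed = 70)
  aln2 <- alignment_from_copies(pl2$copies)
  part2 <- classify_dvns(call_variants(aln2), n_copies = length(pl2$copies))
  hm2 <- haplotype_matrix(part2, names(pl2$copies))
  map2 <- segment_domains(hm2)
  expect_equal(nrow(detect_conversion_tracts(hm2, map2, k_min = 3L)), 0L)
  # no cross-domain runs at all -> empty
  aln3 <- alignment_from_copies(plant_domain_array(seed = 71)$copies)
  part3 <- classify_dvns(call_variants(aln3), n_copies = 40)
  hm3 <- haplotype_matrix(part3, names(plant_domain_array(seed = 71)$copies))
  expect_equal(nrow(detect_conversion_tracts(hm3, segment_domains(hm3))), 0L)
})

test_that("set comparison classifies DVN provenance and sums to the total", {
  pl <- plant_domain_array(seed = 72)
  a <- setNames(pl$copies[1:20], sprintf("A_%02d", 1:20))
  b <- setNames(pl$copies[21:40], sprintf("B_%02d", 1:20))
  cmp <- compare_sets(a, b, joint_alignment = alignment_from_copies(c(a, b)))
  expect_equal(cmp$shared + cmp$private_a + cmp$private_b, cmp$total_dvns)
  # disjoint planted DVN sets: most groups are private
  expect_gt(cmp$private_a + cmp$private_b, cmp$shared)
  # the co-clustering tree has two pure clades
  tree <- ape::read.tree(text = cmp$newick)
  split_a <- grep("^A_", tree$tip.label)
  expect_true(ape::is.monophyletic(tree, tree$tip.label[split_a]))
  # complete separation: raw intermingling is 0
  expect_equal(cmp$intermingling$raw, 0)

  # a set against a copy of itself: no private DVNs
  a2 <- setNames(pl$copies[1:15], sprintf("X_%02d", 1:15))
  b2 <- setNames(pl$copies[1:15], sprintf("Y_%02d", 1:15))
  cmp2 <- compare_sets(a2, b2,
                       joint_alignment = alignment_from_copies(c(a2, b2)))
  expect_equal(cmp2$private_a, 0L)
  expect_equal(cmp2$private_b, 0L)
  expect_gte(cmp2$intermingling$index, 1)
})

test_that("intermingling has the forced values at its boundary cases", {
  # all 20 haplotypes identical: tie-averaging forces raw 10/19, index 1
  m <- matrix(1L, nrow = 10, ncol = 4)
  res <- intermingling_index(m, m, n_perm = 99, seed = 1)
  expect_equal(res$raw, 10 / 19)
  expect_equal(res$index, 1)
  # disjoint haplotype clusters: raw 0
  ma <- matrix(c(1L, 0L), nrow = 6, ncol = 2, byrow = TRUE)
  mb <- matrix(c(0L, 1L), nrow = 6, ncol = 2, byrow = TRUE)
  expect_equal(intermingling_index(ma, mb, n_perm = 99, seed = 1)$raw, 0)
  expect_error(intermingling_index(ma[0, , drop = FALSE], mb, n_perm = 9),
               class = "alphadom_undefined")
})
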