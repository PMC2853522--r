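test_that("exact tandem monomers are tiled perfectly without a consensus", {
  withr::with_seed(11, {
    mono <- paste(sample(c("A", "C", "G", "T"), 171, replace = TRUE),
                  collapse = "")
    arr <- strrep(mono, 10)
  })
  calls <- detect_monomers(arr)
  expect_equal(nrow(calls$calls), 10L)
  expect_true(all(calls$calls$end - calls$calls$start + 1L == 171L))
  expect_true(all(calls$calls$identity_to_consensus == 1))
})

test_that("lightly mutated tandem arrays still tile at the planted boundaries", {
  withr::with_seed(12, {
    mono <- paste(sample(c("A", "C", "G", "T"), 171, replace = TRUE),
                  collapse = "")
    copies <- vapply(1:10, function(i) alphadom:::mutate_fixed(mono, 2),
                     character(1))
    arr <- paste(copies, collapse = "")
  })
  calls <- detect_monomers(arr, monomer_consensus = mono)
  expect_equal(nrow(calls$calls), 10L)
  expect_equal(calls$calls$start, seq(1L, by = 171L, length.out = 10))
  expect_true(all(calls$calls$identity_to_consensus >= 0.97))
})

test_that("monomer calls plus unassigned intervals partition the array", {
  fix <- make_test_hor_record(seed = 21)
  mono <- detect_monomers(fix$record, monomer_consensus = fix$monomer_consensus)
  segs <- rbind(mono$calls[, c("start", "end")], mono$unassigned)
  segs <- segs[order(segs$start), ]
  expect_equal(segs$start[1], 1L)
  expect_equal(segs$end[nrow(segs)], nchar(fix$record$sequence))
  expect_true(all(segs$start[-1] == head(segs$end, -1) + 1L))
})

test_that("the HOR period is recovered from planted arrays and absent from flat ones", {
  fix <- make_test_hor_record(seed = 22, k = 3)
  mono <- detect_monomers(fix$record, monomer_consensus = fix$monomer_consensus)
  period <- infer_hor_period(mono)
  expect_equal(period$k, 3L)
  expect_gt(max(period$lag_profile) - median(period$lag_profile), 0.02)

  # identical monomers: higher-order signal is flat at every lag
  withr::with_seed(13, {
    mono_seq <- paste(sample(c("A", "C", "G", "T"), 171, replace = TRUE),
                      collapse = "")
  })
  flat <- detect_monomers(strrep(mono_seq, 30))
  expect_error(infer_hor_period(flat), class = "alphadom_no_hor_structure")
})

test_that("phasing cuts every k monomers with partial units flagged at the edges", {
  withr::with_seed(14, {
    mono_seq <- paste(sample(c("A", "C", "G", "T"), 171, replace = TRUE),
                      collapse = "")
  })
  mk_calls <- function(n) {
    structure(list(
      calls = data.frame(index = seq_len(n),
                         start = seq(1L, by = 171L, length.out = n),
                         end = seq(171L, by = 171L, length.out = n),
                         identity_to_consensus = 1),
      unassigned = data.frame(start = integer(0), end = integer(0)),
      consensus = mono_seq, array_length = n * 171L,
      array_seq = strrep(mono_seq, n)), class = "monomer_calls")
  }
  ph <- phase_hors(mk_calls(33), k = 11)
  expect_equal(sum(ph$units$complete), 3L)
  expect_equal(nrow(ph$units), 3L)

  # 35 monomers: enumerate all 11 offsets via the complete/partial arithmetic
  for (off in 0:10) {
    n_complete <- (35 - off) %/% 11
    expected_partials <- (off > 0) + ((35 - off) %% 11 > 0)
    ph <- phase_hors(mk_calls(35), k = 11)   # max_homogeneity picks one offset
    expect_equal(sum(ph$units$complete), (35 - ph$anchor_offset) %/% 11)
    expect_equal(sum(!ph$units$complete),
                 (ph$anchor_offset > 0) + ((35 - ph$anchor_offset) %% 11 > 0))
  }
})

test_that("phasing is equivariant under rotation of the array by one monomer", {
  # Site-anchored phase follows the physical units: rotating the array left
  # by one monomer moves the anchor offset down by 1 (mod k).
  fix <- make_test_hor_record(seed = 23, n_units = 10)
  core <- paste(fix$planted$copies[1:6], collapse = "")
  mono <- detect_monomers(core, monomer_consensus = fix$monomer_consensus)
  ph0 <- phase_hors(mono, fix$k, anchor = "restriction_site", site = "AAGCTT")
  rotated <- paste0(substr(core, 172, nchar(core)), substr(core, 1, 171))
  mono_r <- detect_monomers(rotated, monomer_consensus = fix$monomer_consensus)
  ph1 <- phase_hors(mono_r, fix$k, anchor = "restriction_site", site = "AAGCTT")
  expect_equal(ph1$anchor_offset, (ph0$anchor_offset - 1) %% fix$k)
  # the wrapped edge can split at most one unit into two partials
  expect_lte(abs(sum(ph1$units$complete) - sum(ph0$units$complete)), 1L)

  # max-homogeneity phasing is deterministic and cuts complete k-mono units
  phm <- phase_hors(mono, fix$k, anchor = "max_homogeneity")
  expect_true(phm$anchor_offset %in% 0:(fix$k - 1))
  comp <- phm$units[phm$units$complete, ]
  expect_true(all(comp$last_monomer - comp$first_monomer + 1L == fix$k))
})

test_that("restriction-site anchoring places unit starts at the site monomer", {
  fix <- make_test_hor_record(seed = 24)
  mono <- detect_monomers(fix$record, monomer_consensus = fix$monomer_consensus)
  ph <- phase_hors(mono, fix$k, anchor = "restriction_site", site = "AAGCTT")
  comp <- ph$units[ph$units$complete, ]
  first_mono_seqs <- substring(mono$array_seq,
                               mono$calls$start[comp$first_monomer],
                               mono$calls$end[comp$first_monomer])
  expect_gt(mean(grepl("AAGCTT", first_mono_seqs)), 0.5)
  expect_error(phase_hors(mono, fix$k, anchor = "restriction_site",
                          site = "GGGGGGGG"),
               class = "alphadom_anchoring")
})

test_that("in-silico digestion returns the arithmetic fragment lengths", {
  # cut-to-cut distance: 6-bp site + 4 spacer bases = 10-bp internal fragment
  expect_equal(digest_insilico(paste0("AAGCTT", "ACGT", "AAGCTT"), "AAGCTT"),
               c(10L, 6L))
  expect_equal(digest_insilico(strrep("ACGT", 20), "AAGCTT"), 80L)
  # non-palindromic site: both strands cut
  s <- paste0("GGTCTC", strrep("A", 10), "GAGACC", strrep("A", 4))
  expect_equal(sort(digest_insilico(s, "GGTCTC")), c(10L, 16L))
  expect_error(digest_insilico("ACGT", "ACG"), class = "alphadom_parameter")
})

test_that("the homogeneous core is the longest homogeneous run of units", {
  fix <- make_test_hor_record(seed = 25)
  mono <- detect_monomers(fix$record, monomer_consensus = fix$monomer_consensus)
  ph <- phase_hors(mono, fix$k, anchor = "restriction_site", site = "AAGCTT")
  core <- extract_core(ph)
  expect_equal(nrow(core$units), fix$n_units)   # flanks dropped, core kept
  expect_equal(as.integer(names(which.max(table(nchar(core$unit_seqs))))),
               fix$unit_len)

  # all units homogeneous -> the filter is the identity
  all_units <- ph$units[ph$units$complete & ph$units$mean_identity >= 0.95, ]
  expect_equal(core$units$index, all_units$index)
})
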