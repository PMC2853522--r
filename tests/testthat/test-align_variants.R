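test_that("consensus is column majority with the fixed tie order", {
  cons <- build_consensus(c("ACGT", "ACGT", "ACTT"))
  expect_equal(cons$sequence, "ACGT")
  expect_equal(cons$support, c(1, 1, 2 / 3, 1))
  # two-copy tie at one column: A beats C by the fixed order
  tie <- build_consensus(c("AAGT", "ACGT"))
  expect_equal(substr(tie$sequence, 2, 2), "A")
  expect_error(build_consensus(c("ACGT")), class = "alphadom_insufficient_input")
  # gap-majority columns leave consensus coordinates
  gap <- build_consensus(matrix(c("A", "-", "A", "-", "A", "-"), nrow = 3,
                                byrow = TRUE))
  expect_equal(gap$sequence, "A")
})

test_that("a consensus built from noisy copies recovers the ancestor", {
  withr::with_seed(31, {
    anc <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
    copies <- vapply(1:30, function(i) alphadom:::mutate_fixed(anc, 2),
                     character(1))   # ~0.67% divergence each
  })
  cons <- build_consensus(copies)
  expect_gte(mean(chars(cons$sequence) == chars(anc)), 0.999)
})

test_that("anchor alignment projects copies onto consensus columns", {
  withr::with_seed(32, {
    cons_seq <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                      collapse = "")
  })
  cons <- structure(list(sequence = cons_seq, support = rep(1, 120)),
                    class = "consensus")
  identical_copy <- cons_seq
  del_copy <- paste0(substr(cons_seq, 1, 49), substr(cons_seq, 51, 120))
  copies <- c(same = identical_copy, del = del_copy)
  aln <- anchor_align(copies, cons)
  expect_equal(paste(aln$mat["same", ], collapse = ""), cons_seq)
  expect_equal(nrow(aln$insertions), 0L)
  expect_equal(sum(aln$mat["del", ] == "-"), 1L)

  # insertions are recorded against consensus coordinates, not new columns
  ins_copy <- paste0(substr(cons_seq, 1, 60), "A", substr(cons_seq, 61, 120))
  aln2 <- anchor_align(c(same = identical_copy, same2 = identical_copy,
                         ins = ins_copy), cons)
  expect_equal(ncol(aln2$mat), 120L)
  expect_equal(nrow(aln2$insertions), 1L)
  expect_equal(aln2$insertions$copy_id, "ins")

  # hopeless copies raise an outlier error naming the copy
  withr::with_seed(33, junk <- paste(sample(c("A", "C", "G", "T"), 120,
                                            replace = TRUE), collapse = ""))
  expect_error(anchor_align(c(same = identical_copy, bad = junk), cons),
               "bad", class = "alphadom_outlier")
})

test_that("planted per-column states survive alignment projection exactly", {
  pl <- plant_domain_array(n_copies = c(10L, 10L), unit_len = 300,
                           n_dvns = c(8L, 8L), seed = 34)
  aln <- anchor_align(pl$copies)
  truth <- do.call(rbind, strsplit(unname(pl$copies), "", fixed = TRUE))
  expect_equal(unname(aln$mat), truth)
})

test_that("variant calling matches direct cell enumeration", {
  aln <- aln_from_rows(c("ACGT", "ACGT", "ACGT"))
  expect_equal(nrow(call_variants(aln)), 0L)
  aln2 <- aln_from_rows(c("ACGTACGT", "ACGAACGA", "ACGTACGT"))
  v <- call_variants(aln2)
  expect_equal(nrow(v), 2L)
  expect_equal(v$copy_id, rep("copy_02", 2))
  # copies containing N are excluded from calling but stay flagged
  aln3 <- aln_from_rows(c("ACGT", "ANGT", "ACGT"))
  expect_equal(aln3$excluded, "copy_02")
  expect_equal(nrow(call_variants(aln3)), 0L)
})

test_that("DVN classification follows the shared-by-two definition", {
  # copies 1,2 carry T and copy 3 carries G at a consensus-A column
  aln <- aln_from_rows(c("TAAA", "TAAA", "GAAA", "AAAA", "AAAA"))
  part <- classify_dvns(call_variants(aln), n_copies = 5)
  expect_equal(nrow(part$dvns), 1L)
  expect_equal(part$dvns$alt_state, "T")
  expect_equal(part$dvns$carriers[[1]], c("copy_01", "copy_02"))
  expect_equal(nrow(part$sporadic), 1L)
  expect_equal(part$sporadic$alt_state, "G")
  expect_equal(part$dvn_columns, 1L)
  expect_error(classify_dvns(call_variants(aln), 5, min_share = 1),
               class = "alphadom_parameter")
  # nothing shared -> everything sporadic
  aln2 <- aln_from_rows(c("TAAA", "ATAA", "AATA", "AAAA", "AAAA"))
  part2 <- classify_dvns(call_variants(aln2), n_copies = 5)
  expect_equal(nrow(part2$dvns), 0L)
  expect_equal(part2$dvn_columns, 0L)
  expect_equal(nrow(part2$sporadic), 3L)
})

test_that("partition is complete, order-invariant, and monotone in min_share", {
  for (seed in c(41, 42, 43)) {
    mat <- random_alignment(seed)
    aln <- alignment_from_matrix(mat)
    v <- call_variants(aln)
    part <- classify_dvns(v, n_copies = nrow(mat))
    # completeness: every variant in exactly one side
    expect_equal(sum(vapply(part$dvns$carriers, length, integer(1))) +
                   nrow(part$sporadic), nrow(v))
    # copy relabelling/shuffling leaves the (column, state) groups unchanged
    perm <- sample(nrow(mat))
    mat_p <- mat[perm, , drop = FALSE]
    part_p <- classify_dvns(call_variants(alignment_from_matrix(mat_p)),
                            n_copies = nrow(mat))
    expect_equal(part_p$dvns[, c("column", "alt_state", "n_carriers")],
                 part$dvns[, c("column", "alt_state", "n_carriers")])
    # raising min_share never increases the number of DVN groups
    sizes <- vapply(2:4, function(ms)
      nrow(classify_dvns(v, nrow(mat), min_share = ms)$dvns), integer(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("sporadic rate is the singleton fraction of aligned cells", {
  aln <- aln_from_rows(rep(strrep("ACGT", 25), 10))
  part <- classify_dvns(call_variants(aln), n_copies = 10)
  expect_equal(sporadic_rate(part, aln)$rate_pct, 0)

  # 10 copies x 100 columns with 5 singletons -> 0.5%
  rows <- rep(strrep("A", 100), 10)
  for (i in 1:5) substr(rows[i], i * 10, i * 10) <- "C"
  aln2 <- aln_from_rows(rows)
  part2 <- classify_dvns(call_variants(aln2), n_copies = 10)
  r <- sporadic_rate(part2, aln2)
  expect_equal(r$rate_pct, 0.5)
  expect_equal(unname(r$per_copy_pct[1:5]), rep(1, 5))
})

test_that("CENP-B box scanning scores the nine essential positions", {
  box <- "ATTCGTTGGAAACGGGA"
  m_intact <- paste0(strrep("T", 40), box, strrep("T", 40))
  res <- scan_cenpb(m_intact)
  expect_true(res$intact)
  expect_equal(res$n_essential_matches, 9L)
  expect_equal(res$offset, 41L)

  m_broken <- sub("CGGG", "CAGG", m_intact, fixed = TRUE)
  res2 <- scan_cenpb(m_broken)
  expect_false(res2$intact)
  expect_equal(res2$n_essential_matches, 8L)

  # planted essential-position damage is counted exactly
  ess <- c(2, 3, 4, 5, 10, 13, 14, 15, 16)
  flip <- function(s, k) {   # damage the first k essential positions
    x <- chars(s)
    for (p in ess[seq_len(k)]) x[40 + p] <- setdiff(c("A", "C", "G", "T"), x[40 + p])[1]
    paste(x, collapse = "")
  }
  planted <- vapply(0:4, function(k) flip(m_intact, k), character(1))
  got <- scan_cenpb(planted)
  expect_equal(got$n_essential_matches, 9L - (0:4))
  expect_error(scan_cenpb("ACGTACGT"), class = "alphadom_validation")
})
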