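## Shared fixtures and independent oracles. Everything is generated in code.

aln_from_rows <- function(rows, ids = sprintf("copy_%02d", seq_along(rows))) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(mat) <- ids
  alignment_from_matrix(mat)
}

## Independent brute-force DVN oracle: plain double loops, no shared code
## with the implementation beyond the published definition (majority
## consensus with tie order A<C<G<T<'-'; a DVN is a (column, state) shared
## by >= min_share copies; everything else is sporadic).
oracle_partition <- function(mat, min_share = 2L) {
  states <- c("A", "C", "G", "T", "-")
  ncols <- ncol(mat)
  cons <- character(ncols)
  for (j in seq_len(ncols)) {
    best <- ""; best_n <- -1L
    for (s in states) {
      n <- 0L
      for (i in seq_len(nrow(mat))) if (mat[i, j] == s) n <- n + 1L
      if (n > best_n) { best_n <- n; best <- s }
    }
    cons[j] <- best
  }
  var_copy <- character(0); var_col <- integer(0); var_alt <- character(0)
  for (j in seq_len(ncols)) {
    for (i in seq_len(nrow(mat))) {
      if (mat[i, j] != cons[j]) {
        var_copy <- c(var_copy, rownames(mat)[i])
        var_col <- c(var_col, j)
        var_alt <- c(var_alt, mat[i, j])
      }
    }
  }
  key <- paste(var_col, var_alt)
  counts <- table(key)
  is_dvn <- counts[key] >= min_share
  dvn_groups <- sort(unique(key[is_dvn]))
  carriers <- lapply(dvn_groups, function(k) sort(var_copy[key == k]))
  names(carriers) <- dvn_groups
  list(
    variants = data.frame(copy_id = var_copy, column = var_col,
                          alt_state = var_alt)[order(var_col, var_copy), ],
    dvn_groups = dvn_groups,
    carriers = carriers,
    dvn_columns = length(unique(var_col[is_dvn])),
    n_sporadic = sum(!is_dvn)
  )
}

random_alignment <- function(seed) {
  set.seed(seed)
  n <- sample(2:8, 1)
  m <- sample(5:60, 1)
  base <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  mat <- matrix(rep(base, n), nrow = n, byrow = TRUE)
  nmut <- rpois(1, 0.15 * n * m)
  for (k in seq_len(nmut)) {
    i <- sample.int(n, 1); j <- sample.int(m, 1)
    mat[i, j] <- sample(c("A", "C", "G", "T", "-"), 1)
  }
  rownames(mat) <- sprintf("copy_%02d", seq_len(n))
  mat
}

## Small tandem-HOR array with planted domain structure, for decompose and
## pipeline tests: k monomer families (171 bp, ~15% diverged from a shared
## base carrying one HindIII site), n_units copies in two planted domains,
## two divergent flanking units per side.
make_test_hor_record <- function(seed = 1L, n_units = 24L, k = 3L,
                                 n_dvns = c(15L, 15L)) {
  withr::with_seed(seed, {
    base <- paste(sample(c("A", "C", "G", "T"), 171, replace = TRUE),
                  collapse = "")
    base <- alphadom:::scrub_site(base, "AAGCTT")
    substr(base, 31, 36) <- "AAGCTT"
    fams <- vapply(seq_len(k), function(f) {
      fam <- alphadom:::mutate_fixed(base, 26,
                                     protect = if (f == 1) 31:36 else integer(0))
      alphadom:::scrub_site(fam, "AAGCTT", keep_at = if (f == 1) 31L else integer(0))
    }, character(1))
    ancestor <- paste(fams, collapse = "")
    pl <- plant_domain_array(n_copies = c(n_units / 2, n_units / 2),
                             unit_len = nchar(ancestor), n_dvns = n_dvns,
                             seed = sample.int(1e6, 1), ancestor = ancestor,
                             protect = 31:36)   # keep the HindIII site intact
    flank <- function() alphadom:::mutate_fixed(ancestor, round(0.1 * nchar(ancestor)))
    seqfull <- paste(c(flank(), flank(), unname(pl$copies), flank(), flank()),
                     collapse = "")
    list(record = alphadom:::new_seq_records("test_array", seqfull, "helper"),
         monomer_consensus = base, ancestor = ancestor, planted = pl,
         unit_len = nchar(ancestor), k = k, n_units = n_units)
  })
}

## The full synthetic archetype and its pipeline products are expensive
## (~30 s); build once per test run and share.
.arch_cache <- new.env(parent = emptyenv())

archetype_fixture <- function() {
  if (is.null(.arch_cache$arch)) .arch_cache$arch <- sim_archetype_array(seed = 101L)
  .arch_cache$arch
}

archetype_results <- function() {
  if (is.null(.arch_cache$res)) {
    arch <- archetype_fixture()
    mono <- detect_monomers(arch$record,
                            monomer_consensus = arch$monomer_consensus)
    period <- infer_hor_period(mono)
    phasing <- phase_hors(mono, period$k, anchor = "restriction_site",
                          site = arch$site)
    core <- extract_core(phasing)
    aln <- anchor_align(core$unit_seqs)
    part <- classify_dvns(call_variants(aln), n_copies = nrow(aln$mat))
    hm <- haplotype_matrix(part, aln$copy_ids)
    map <- detect_barriers(segment_domains(hm), hm)
    .arch_cache$res <- list(
      mono = mono, period = period, phasing = phasing, core = core,
      aln = aln, part = part, hm = hm, map = map,
      fragments = digest_insilico(arch$record, arch$site),
      rate = sporadic_rate(part, aln),
      pairs = detect_duplicate_pairs(aln, part)
    )
  }
  .arch_cache$res
}
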