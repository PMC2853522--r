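## hor_decompose: turn raw array sequence into positioned ~171-bp monomers
## and phased higher-order repeat (HOR) units, find the HOR period, run
## in-silico restriction digests, and extract the homogeneous core.
##
## All coordinates are 1-based closed intervals on the array sequence.

#' Derive a monomer consensus from the array itself
#'
#' The monomer period is found by maximising the autocorrelation of exact
#' 8-mer matches over lags 150-200 bp; a seed window of that length is then
#' tiled across the array and the called instances are majority-voted into a
#' consensus. Re-tiling (rather than chopping the array at a fixed lag) keeps
#' the phase honest when monomer lengths vary by a few bases.
#'
#' @param array_seq DNA string of the array.
#' @param lag_range Candidate monomer lengths (default 150:200).
#' @param min_signal Minimum 8-mer autocorrelation at the best lag before the
#'   array is declared non-periodic (default 0.005).
#' @return List with `consensus` (DNA string) and `lag_profile`.
#' @export
derive_monomer_consensus <- function(array_seq, lag_range = 150:200,
                                     min_signal = 0.005) {
  x <- chars(array_seq)
  n <- length(x)
  if (n < 2 * max(lag_range)) {
    adom_stop("array too short to derive a monomer consensus", "decomposition_failure")
  }
  score <- vapply(lag_range, function(L) {
    m <- x[seq_len(n - L)] == x[(L + 1):n]
    cs <- cumsum(m)
    k <- length(m) - 7L
    if (k < 1) return(0)
    win <- cs[8:length(m)] - c(0, cs[seq_len(k - 1)])
    mean(win == 8L)
  }, numeric(1))
  best <- which.max(score)
  if (score[best] < min_signal) {
    adom_stop("no periodic monomer signal in the 150-200 bp lag range",
              "decomposition_failure")
  }
  L <- lag_range[best]
  # seed at the centre of the array, then one tiling pass + majority vote
  seed_start <- max(1L, floor(n / 2) - floor(L / 2))
  seed <- substr(array_seq, seed_start, seed_start + L - 1L)
  calls <- tile_monomers(array_seq, seed, min_identity = 0.5, slack = 15L,
                         wide_first = TRUE)
  inst <- substring(array_seq, calls$start, calls$end)
  lens <- nchar(inst)
  modal <- as.integer(names(which.max(table(lens))))
  inst <- inst[lens == modal]
  if (length(inst) < 5) {
    adom_stop("fewer than 5 tandem monomers recovered; supply a monomer consensus",
              "decomposition_failure")
  }
  mat <- do.call(rbind, strsplit(inst, "", fixed = TRUE))
  cons <- paste(column_majority(mat)$state, collapse = "")
  # canonicalise the (arbitrary) rotation of the consensus so that tiling
  # anchors at the first monomer boundary of the array
  head_win <- substr(array_seq, 1L, min(n, 2L * nchar(cons)))
  pa <- Biostrings::pairwiseAlignment(
    cons, head_win, type = "global-local",
    substitutionMatrix = .submat(), gapOpening = 4, gapExtension = 1)
  s <- (Biostrings::start(Biostrings::subject(pa)) - 1L) %% nchar(cons) + 1L
  if (s > 1) {
    cons <- paste0(substr(cons, nchar(cons) - s + 2L, nchar(cons)),
                   substr(cons, 1L, nchar(cons) - s + 1L))
  }
  list(consensus = cons, lag_profile = setNames(score, lag_range))
}

## Greedy left-to-right tiling of the array by semi-global consensus matches.
## The first window normally allows placements only within `slack` of the
## array start, anchoring tiling deterministically at the first acceptable
## boundary; `wide_first` widens it to two monomer lengths for the
## phase-free seed pass of consensus self-derivation.
tile_monomers <- function(array_seq, consensus, min_identity = 0.60,
                          slack = 15L, wide_first = FALSE) {
  n <- nchar(array_seq)
  L <- nchar(consensus)
  starts <- integer(0); ends <- integer(0); idents <- numeric(0)
  expected <- 1L
  first <- TRUE
  while (expected <= n - floor(0.6 * L)) {
    prev_end <- if (length(ends)) ends[length(ends)] else 0L
    # window never reaches back over an accepted call: calls stay non-overlapping
    ws <- if (first) 1L else max(1L, expected - slack, prev_end + 1L)
    we <- if (first && wide_first) min(n, 2L * L + slack)
          else min(n, expected + L + slack)
    if (we - ws + 1L < floor(0.6 * L)) break
    window <- substr(array_seq, ws, we)
    pa <- Biostrings::pairwiseAlignment(
      consensus, window, type = "global-local",
      substitutionMatrix = .submat(), gapOpening = 4, gapExtension = 1
    )
    ident <- Biostrings::pid(pa) / 100
    st <- ws + Biostrings::start(Biostrings::subject(pa)) - 1L
    en <- ws + Biostrings::end(Biostrings::subject(pa)) - 1L
    if (ident >= min_identity && (length(ends) == 0 || st > ends[length(ends)])) {
      starts <- c(starts, st); ends <- c(ends, en); idents <- c(idents, ident)
      expected <- en + 1L
    } else {
      expected <- expected + L   # unassigned stretch; keep scanning
    }
    first <- FALSE
  }
  data.frame(index = seq_along(starts), start = starts, end = ends,
             identity_to_consensus = idents)
}

#' Detect alpha-satellite monomers along an array
#'
#' Greedy non-overlapping tiling of the array by semi-global matches to the
#' monomer consensus (self-derived when not supplied), accepting matches at or
#' above `min_identity`, each search window centred within +/- `slack` bp of
#' the expected next start. Gaps between consecutive calls are reported as
#' unassigned intervals; calls plus unassigned intervals exactly partition the
#' array.
#'
#' @param array A DNA string, one-row `seq_records`, or named character vector.
#' @param monomer_consensus Optional monomer consensus DNA string.
#' @param min_identity Minimum identity for an accepted call (default 0.60).
#' @param slack Positional slack around the expected next start (default 15).
#' @return A `monomer_calls` object: list with `calls` (data frame `index`,
#'   `start`, `end`, `identity_to_consensus`), `unassigned`, `consensus`,
#'   `array_length`.
#' @export
detect_monomers <- function(array, monomer_consensus = NULL,
                            min_identity = 0.60, slack = 15L) {
  seqv <- as_dna(array)
  array_seq <- unname(seqv[[1]])
  if (is.null(monomer_consensus)) {
    monomer_consensus <- derive_monomer_consensus(array_seq)$consensus
  }
  if (nchar(array_seq) < 2 * nchar(monomer_consensus)) {
    adom_stop("array shorter than two monomer lengths", "decomposition_failure")
  }
  calls <- tile_monomers(array_seq, monomer_consensus, min_identity, slack)
  if (nrow(calls) == 0) {
    adom_stop("no monomer matched the consensus at the identity threshold",
              "decomposition_failure")
  }
  structure(
    list(calls = calls,
         unassigned = interval_complement(calls$start, calls$end, nchar(array_seq)),
         consensus = monomer_consensus,
         array_length = nchar(array_seq),
         array_seq = array_seq),
    class = "monomer_calls"
  )
}

#' @export
print.monomer_calls <- function(x, ...) {
  cat(sprintf("<monomer_calls> %d monomers (modal length %d bp) on a %d bp array; %d unassigned interval(s)\n",
              nrow(x$calls),
              as.integer(names(which.max(table(x$calls$end - x$calls$start + 1L)))),
              x$array_length, nrow(x$unassigned)))
  invisible(x)
}

monomer_seqs <- function(monomers) {
  substring(monomers$array_seq, monomers$calls$start, monomers$calls$end)
}

#' Infer the HOR period (monomers per higher-order unit)
#'
#' For each candidate lag k the mean pairwise identity between monomer i and
#' monomer i+k is computed (subsampled to `max_pairs` pairs per lag); the
#' period is the smallest lag within a contrast-scaled band of the profile
#' maximum — multiples of the true period score equally well, so the bare
#' argmax would be unstable. A flat profile (maximum minus
#' median below `min_contrast`) means no higher-order structure — e.g. an
#' array of identical monomers, where every lag scores the same.
#'
#' @param monomers A `monomer_calls` object.
#' @param k_max Largest candidate period (default 30).
#' @param max_pairs Pairs sampled per lag (default 50).
#' @param min_contrast Required max-minus-median contrast (default 0.02).
#' @return List with `k` and `lag_profile` (named numeric).
#' @export
infer_hor_period <- function(monomers, k_max = 30L, max_pairs = 50L,
                             min_contrast = 0.02) {
  seqs <- monomer_seqs(monomers)
  n <- length(seqs)
  k_hi <- min(k_max, n - 2L)
  if (k_hi < 2L || n < 6L) {
    adom_stop("too few monomers to test candidate HOR periods", "no_hor_structure")
  }
  prof <- vapply(2:k_hi, function(k) {
    i <- seq_len(n - k)
    if (length(i) > max_pairs) i <- round(seq(1, n - k, length.out = max_pairs))
    mean(vapply(i, function(ii) seq_identity(seqs[ii], seqs[ii + k]), numeric(1)))
  }, numeric(1))
  names(prof) <- 2:k_hi
  if (max(prof) - median(prof) < min_contrast) {
    adom_stop("lag-identity profile is flat: no higher-order repeat structure",
              "no_hor_structure")
  }
  # multiples of the true period score (nearly) as well as the period itself:
  # take the smallest lag within a contrast-scaled band of the maximum
  eps <- min(0.05, (max(prof) - median(prof)) / 3)
  near <- which(prof >= max(prof) - eps)
  list(k = as.integer(names(prof)[near[1]]), lag_profile = prof)
}

#' Phase monomers into HOR units
#'
#' Units are cut every `k` monomers starting at an anchor offset. With
#' `anchor = "restriction_site"` the unit start is the monomer containing the
#' first base of the recognition site (modal phase over all site-bearing
#' monomers); with `anchor = "max_homogeneity"` the offset maximising mean
#' adjacent unit-to-unit identity is chosen (ties to the smaller offset).
#' Leading/trailing runs shorter than k monomers become units flagged
#' `complete = FALSE`. Each complete unit's `mean_identity` is its identity
#' to the majority consensus of all complete units.
#'
#' @param monomers A `monomer_calls` object.
#' @param k HOR period from [infer_hor_period()].
#' @param anchor `"max_homogeneity"` or `"restriction_site"`.
#' @param site Recognition sequence (required for restriction anchoring);
#'   HindIII is `"AAGCTT"`.
#' @return A `hor_phasing` object: `k`, `anchor_offset`, `units` data frame
#'   (`index`, `start`, `end`, `first_monomer`, `last_monomer`, `complete`,
#'   `mean_identity`), and `unit_seqs`.
#' @export
phase_hors <- function(monomers, k,
                       anchor = c("max_homogeneity", "restriction_site"),
                       site = NULL) {
  anchor <- match.arg(anchor)
  calls <- monomers$calls
  n <- nrow(calls)
  if (k < 2) adom_stop("HOR period k must be >= 2", "parameter")
  if (n < k) adom_stop("fewer monomers than one HOR period", "parameter")

  unit_table <- function(offset) {
    # offset in [0, k): first complete unit starts at monomer offset+1
    if (offset + k <= n) {
      first_starts <- seq(offset + 1L, n - k + 1L, by = k)
    } else {
      first_starts <- integer(0)
    }
    units <- data.frame(first_monomer = first_starts,
                        last_monomer = first_starts + k - 1L,
                        complete = rep(TRUE, length(first_starts)))
    if (offset > 0) {
      units <- rbind(data.frame(first_monomer = 1L, last_monomer = as.integer(offset),
                                complete = FALSE), units)
    }
    last_used <- if (nrow(units)) units$last_monomer[nrow(units)] else 0L
    if (last_used < n) {
      units <- rbind(units, data.frame(first_monomer = last_used + 1L,
                                       last_monomer = n, complete = FALSE))
    }
    units
  }
  unit_seq <- function(u) substring(monomers$array_seq,
                                    calls$start[u$first_monomer],
                                    calls$end[u$last_monomer])

  if (anchor == "restriction_site") {
    if (is.null(site)) adom_stop("restriction_site anchoring needs a site", "parameter")
    occ <- Biostrings::start(Biostrings::matchPattern(site, monomers$array_seq))
    mono_of <- findInterval(occ, calls$start)
    mono_of <- mono_of[mono_of >= 1 & occ <= calls$end[pmax(mono_of, 1)]]
    if (length(mono_of) == 0) {
      adom_stop("restriction site not found in any monomer; try anchor = 'max_homogeneity'",
                "anchoring")
    }
    phase <- (mono_of - 1L) %% k
    offset <- as.integer(names(which.max(table(phase))))
    units <- unit_table(offset)
    comp <- units[units$complete, , drop = FALSE]
    with_site <- vapply(seq_len(nrow(comp)), function(i) {
      any(mono_of >= comp$first_monomer[i] & mono_of <= comp$last_monomer[i])
    }, logical(1))
    if (mean(with_site) < 0.5) {
      adom_stop("restriction site absent from >= 50% of candidate units; try anchor = 'max_homogeneity'",
                "anchoring")
    }
  } else {
    offs <- 0:(k - 1L)
    hom <- vapply(offs, function(o) {
      u <- unit_table(o)
      u <- u[u$complete, , drop = FALSE]
      if (nrow(u) < 2) return(-Inf)
      sq <- vapply(seq_len(nrow(u)), function(i) unit_seq(u[i, ]), character(1))
      mean(vapply(seq_len(length(sq) - 1L),
                  function(i) seq_identity(sq[i], sq[i + 1]), numeric(1)))
    }, numeric(1))
    offset <- offs[which.max(hom)]
    units <- unit_table(offset)
  }

  units$index <- seq_len(nrow(units))
  units$start <- calls$start[units$first_monomer]
  units$end <- calls$end[units$last_monomer]
  sq <- vapply(seq_len(nrow(units)), function(i) unit_seq(units[i, ]), character(1))
  comp_idx <- which(units$complete)
  units$mean_identity <- NA_real_
  if (length(comp_idx) >= 2) {
    ucons <- build_consensus(sq[comp_idx])$sequence
    units$mean_identity[comp_idx] <- vapply(comp_idx,
      function(i) seq_identity(sq[i], ucons), numeric(1))
  }
  units <- units[, c("index", "start", "end", "first_monomer", "last_monomer",
                     "complete", "mean_identity")]
  structure(list(k = as.integer(k), anchor_offset = as.integer(offset),
                 units = units, unit_seqs = sq,
                 array_seq = monomers$array_seq),
            class = "hor_phasing")
}

#' @export
print.hor_phasing <- function(x, ...) {
  cat(sprintf("<hor_phasing> k = %d, anchor offset %d: %d unit(s), %d complete\n",
              x$k, x$anchor_offset, nrow(x$units), sum(x$units$complete)))
  invisible(x)
}

#' In-silico restriction digest
#'
#' Fragment lengths between successive occurrences of the recognition site on
#' the forward strand (plus both flanking fragments); for a non-palindromic
#' site, reverse-strand occurrences are included. Cutting is modelled at the
#' first base of the site. No occurrence yields a single fragment equal to the
#' array length.
#'
#' @param array DNA string (or one-row `seq_records`).
#' @param site Recognition sequence, length >= 4.
#' @return Integer vector of fragment lengths (zero-length flanks dropped).
#' @export
digest_insilico <- function(array, site) {
  seqv <- as_dna(array)
  array_seq <- unname(seqv[[1]])
  if (nchar(site) < 4) adom_stop("restriction site must be >= 4 bp", "parameter")
  occ <- Biostrings::start(Biostrings::matchPattern(site, array_seq))
  if (!identical(site, reverse_complement(site))) {
    occ <- sort(unique(c(occ,
      Biostrings::start(Biostrings::matchPattern(reverse_complement(site), array_seq)))))
  }
  n <- nchar(array_seq)
  if (length(occ) == 0) return(as.integer(n))
  frags <- c(occ[1] - 1L, diff(occ), n - occ[length(occ)] + 1L)
  as.integer(frags[frags > 0])
}

#' Extract the homogeneous HOR core
#'
#' The longest contiguous run of complete units whose identity to the unit
#' consensus is at least `1 - max_divergence`; flanking divergent units (and
#' partial edge units) are dropped. This mirrors the structure of real arrays,
#' whose central part is highly homogeneous while the sides diverge.
#'
#' @param phasing A `hor_phasing` object.
#' @param max_divergence Maximum unit-to-consensus divergence (default 0.05).
#' @return A `hor_core` object: `units` (subset of the phasing table),
#'   `unit_seqs` (named `unit_<index>`), `k`.
#' @export
extract_core <- function(phasing, max_divergence = 0.05) {
  u <- phasing$units
  ok <- u$complete & !is.na(u$mean_identity) & u$mean_identity >= 1 - max_divergence
  if (!any(ok)) adom_stop("no unit passes the core homogeneity filter", "empty_core")
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  idx <- starts[best]:ends[best]
  seqs <- phasing$unit_seqs[idx]
  names(seqs) <- sprintf("unit_%03d", seq_along(idx))
  structure(list(units = u[idx, , drop = FALSE], unit_seqs = seqs,
                 k = phasing$k),
            class = "hor_core")
}

#' @export
print.hor_core <- function(x, ...) {
  cat(sprintf("<hor_core> %d contiguous homogeneous units of %d monomers\n",
              nrow(x$units), x$k))
  invisible(x)
}
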