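## align_variants: project near-identical HOR copies onto a consensus
## coordinate system, call per-copy variants, split them into Diagnostic
## Variant Nucleotides (DVNs, shared by >= 2 copies) versus sporadic
## singletons, and scan CENP-B boxes.

ALN_STATES <- c("A", "C", "G", "T", "-")

## ---------------------------------------------------------------- consensus

#' Build a majority-rule consensus from repeat copies
#'
#' Column-wise majority state over an alignment; columns whose majority state
#' is a gap are removed from consensus coordinates. Ties are broken by the
#' fixed order A < C < G < T < '-'. Unaligned equal-length copies are treated
#' as pre-stacked columns; for unequal lengths the copies of modal length
#' seed the consensus (which [anchor_align()] then re-estimates).
#'
#' @param copies Named character vector / `seq_records` of copies, a character
#'   matrix of aligned states, or an [array_alignment].
#' @return A `consensus` object: list with `sequence` (DNA string) and
#'   `support` (per-column fraction of copies matching the consensus state).
#' @export
build_consensus <- function(copies) {
  mat <- NULL
  if (inherits(copies, "array_alignment")) {
    mat <- copies$mat
  } else if (is.matrix(copies)) {
    mat <- copies
  } else {
    seqs <- as_dna(copies)
    if (length(seqs) < 2) {
      adom_stop("need at least 2 copies to build a consensus", "insufficient_input")
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) {
      modal <- as.integer(names(which.max(table(lens))))
      seqs <- seqs[lens == modal]
      if (length(seqs) < 2) seqs <- rep(seqs, 2L)
    }
    mat <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  }
  if (nrow(mat) < 2) {
    adom_stop("need at least 2 copies to build a consensus", "insufficient_input")
  }
  maj <- column_majority(mat)
  keep <- maj$state != "-"
  structure(
    list(sequence = paste(maj$state[keep], collapse = ""),
         support = maj$support[keep]),
    class = "consensus"
  )
}

## Majority state per column with fixed tie order A<C<G<T<'-'; 'N' never wins.
column_majority <- function(mat) {
  state <- character(ncol(mat))
  support <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[col != "N"]
    if (length(col) == 0) { state[j] <- "N"; support[j] <- 0; next }
    counts <- vapply(ALN_STATES, function(s) sum(col == s), integer(1))
    w <- which(counts == max(counts))[1]   # ALN_STATES order breaks ties
    state[j] <- ALN_STATES[w]
    support[j] <- counts[w] / length(col)
  }
  list(state = state, support = support)
}

#' @export
print.consensus <- function(x, ...) {
  cat(sprintf("<consensus> %d columns, mean support %.3f\n",
              nchar(x$sequence), mean(x$support)))
  invisible(x)
}

## --------------------------------------------------------------- alignment

new_array_alignment <- function(mat, consensus_state, support, insertions,
                                excluded = character(0)) {
  structure(
    list(copy_ids = rownames(mat), mat = mat,
         consensus = consensus_state, support = support,
         insertions = insertions, excluded = excluded),
    class = "array_alignment"
  )
}

#' Build an alignment object from a pre-aligned state matrix
#'
#' Rows are copies, columns alignment positions, states in \{A,C,G,T,-,N\}.
#' The consensus is recomputed by column majority; gap-majority columns stay
#' in the matrix (so round trips through alignment files are lossless) but
#' carry a '-' consensus state.
#'
#' @param mat Character matrix with row names as copy ids.
#' @export
alignment_from_matrix <- function(mat) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("copy_%d", seq_len(nrow(mat)))
  maj <- column_majority(mat)
  excluded <- rownames(mat)[apply(mat == "N", 1, any)]
  new_array_alignment(
    mat, maj$state, maj$support,
    data.frame(copy_id = character(0), column = integer(0),
               inserted = character(0), stringsAsFactors = FALSE),
    excluded
  )
}

#' @export
print.array_alignment <- function(x, ...) {
  cat(sprintf("<array_alignment> %d copies x %d columns; %d insertion(s); %d copy(ies) with N excluded from variant calling\n",
              nrow(x$mat), ncol(x$mat), nrow(x$insertions), length(x$excluded)))
  invisible(x)
}

#' Build an alignment directly from equal-length ungapped copies
#'
#' When copies share one length and contain no indels (e.g. simulator output
#' with substitutions only), they already sit in a common coordinate system
#' and stacking them is the alignment. For anything else use [anchor_align()].
#'
#' @param copies Named character vector / `seq_records` of equal-length copies.
#' @export
alignment_from_copies <- function(copies) {
  seqs <- as_dna(copies)
  if (length(unique(nchar(seqs))) != 1) {
    adom_stop("copies differ in length; use anchor_align()", "validation")
  }
  mat <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  alignment_from_matrix(mat)
}

#' Anchor near-identical copies onto a consensus coordinate system
#'
#' Each copy is globally aligned to the consensus with affine gap penalties
#' (match +1, mismatch -1, gap open 4, gap extend 1) and its states are
#' projected onto consensus columns; copy bases opposite consensus gaps are
#' recorded as insertions rather than new columns, keeping the coordinate
#' system fixed. The consensus is re-estimated once from the projected matrix
#' and copies realigned if it changed.
#'
#' @param copies Named character vector or `seq_records` of copies.
#' @param consensus Optional `consensus` object; derived from the copies when
#'   missing.
#' @param min_identity Copies aligning below this identity raise an outlier
#'   error naming the copy (default 0.60).
#' @return An [array_alignment].
#' @export
anchor_align <- function(copies, consensus = NULL, min_identity = 0.60) {
  seqs <- as_dna(copies)
  if (length(seqs) == 0) adom_stop("no copies to align", "empty_input")
  if (is.null(consensus)) consensus <- build_consensus(seqs)
  cons <- consensus$sequence
  bad_len <- abs(nchar(seqs) - nchar(cons)) / nchar(cons) > 0.20
  if (any(bad_len)) {
    adom_stop(sprintf("copy '%s' differs from consensus length by more than 20%%",
                      names(seqs)[which(bad_len)[1]]), "validation")
  }
  res <- project_copies(seqs, cons, min_identity)
  maj <- column_majority(res$mat)
  new_cons <- paste(maj$state[maj$state != "-"], collapse = "")
  if (!identical(new_cons, cons)) {
    res <- project_copies(seqs, new_cons, min_identity)
    maj <- column_majority(res$mat)
  }
  new_array_alignment(res$mat, maj$state, maj$support, res$insertions,
                      rownames(res$mat)[apply(res$mat == "N", 1, any)])
}

project_copies <- function(seqs, cons, min_identity) {
  ncols <- nchar(cons)
  mat <- matrix("-", nrow = length(seqs), ncol = ncols,
                dimnames = list(names(seqs), NULL))
  ins <- list()
  pas <- Biostrings::pairwiseAlignment(
    unname(seqs), cons, type = "global",
    substitutionMatrix = .submat(), gapOpening = 4, gapExtension = 1
  )
  pstr <- as.character(Biostrings::alignedPattern(pas))
  sstr <- as.character(Biostrings::alignedSubject(pas))
  ident <- Biostrings::pid(pas) / 100
  low <- ident < min_identity
  if (any(low)) {
    adom_stop(sprintf("copy '%s' aligns to the consensus at %.1f%% identity (< %.0f%%)",
                      names(seqs)[which(low)[1]], 100 * ident[which(low)[1]],
                      100 * min_identity), "outlier")
  }
  for (i in seq_along(seqs)) {
    p <- chars(pstr[i]); s <- chars(sstr[i])
    if (!any(s == "-")) {           # no insertions: states project 1:1
      mat[i, ] <- p
      next
    }
    j <- 0L
    for (k in seq_along(s)) {
      if (s[k] != "-") {
        j <- j + 1L
        mat[i, j] <- p[k]
      } else {
        ins[[length(ins) + 1L]] <- list(copy_id = names(seqs)[i],
                                        column = j, inserted = p[k])
      }
    }
  }
  insertions <- if (length(ins)) {
    raw <- do.call(rbind, lapply(ins, as.data.frame, stringsAsFactors = FALSE))
    # merge adjacent single-base insertion records at the same column
    agg <- stats::aggregate(inserted ~ copy_id + column, data = raw,
                            FUN = paste, collapse = "")
    agg[order(agg$copy_id, agg$column), , drop = FALSE]
  } else {
    data.frame(copy_id = character(0), column = integer(0),
               inserted = character(0), stringsAsFactors = FALSE)
  }
  rownames(insertions) <- NULL
  list(mat = mat, insertions = insertions)
}

## ----------------------------------------------------------------- variants

#' Call per-copy variants against the alignment consensus
#'
#' One variant per (copy, column) cell whose state differs from the consensus
#' state at that column. Copies containing 'N' are excluded from calling
#' (they stay flagged in `alignment$excluded`); insertions are reported in
#' the alignment object but never enter the variant list.
#'
#' @param alignment An [array_alignment].
#' @return Data frame with columns `copy_id`, `column`, `alt_state`.
#' @export
call_variants <- function(alignment) {
  mat <- alignment$mat
  keep <- !(rownames(mat) %in% alignment$excluded)
  mat <- mat[keep, , drop = FALSE]
  cons <- alignment$consensus
  hits <- which(sweep(mat, 2, cons, FUN = "!="), arr.ind = TRUE)
  out <- data.frame(
    copy_id = rownames(mat)[hits[, 1]],
    column = as.integer(hits[, 2]),
    alt_state = mat[hits],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$column, out$copy_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition variants into DVNs and sporadic mutations
#'
#' A (column, alternative state) group carried by at least `min_share` copies
#' is a Diagnostic Variant Nucleotide (DVN); all remaining variants are
#' sporadic singletons. Deletions ('-') are DVN-eligible states. The headline
#' statistic `dvn_columns` counts distinct consensus positions bearing at
#' least one DVN group (a position can host two DVN groups with different
#' alternative states).
#'
#' @param variants Data frame from [call_variants()].
#' @param n_copies Number of copies in the alignment the variants came from.
#' @param min_share Minimum carriers for DVN status (default 2; values < 2
#'   are rejected).
#' @return A `variant_partition` object.
#' @export
classify_dvns <- function(variants, n_copies, min_share = 2L) {
  if (min_share < 2) {
    adom_stop("min_share must be >= 2: a DVN is by definition shared", "parameter")
  }
  key <- paste(variants$column, variants$alt_state, sep = "|")
  tab <- table(key)
  is_dvn <- tab[key] >= min_share
  dvn_rows <- variants[is_dvn, , drop = FALSE]
  spo_rows <- variants[!is_dvn, , drop = FALSE]
  dvns <- if (nrow(dvn_rows)) {
    sp <- split(dvn_rows$copy_id, paste(dvn_rows$column, dvn_rows$alt_state, sep = "|"))
    keys <- names(sp)
    col <- as.integer(sub("\\|.*$", "", keys))
    alt <- sub("^.*\\|", "", keys)
    o <- order(col, alt)
    data.frame(
      column = col[o], alt_state = alt[o],
      n_carriers = vapply(sp[o], length, integer(1)),
      carriers = I(unname(sp[o])),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(column = integer(0), alt_state = character(0),
               n_carriers = integer(0), carriers = I(list()))
  }
  rownames(dvns) <- NULL
  rownames(spo_rows) <- NULL
  structure(
    list(dvns = dvns, sporadic = spo_rows,
         dvn_columns = length(unique(dvns$column)),
         n_copies = as.integer(n_copies)),
    class = "variant_partition"
  )
}

#' @export
print.variant_partition <- function(x, ...) {
  cat(sprintf("<variant_partition> %d DVN group(s) at %d position(s); %d sporadic mutation(s); %d copies\n",
              nrow(x$dvns), x$dvn_columns, nrow(x$sporadic), x$n_copies))
  invisible(x)
}

#' Flatten a variant partition to a table (copy_id, column, alt_state, class)
#' @param x A `variant_partition`.
#' @param ... Unused.
#' @export
as.data.frame.variant_partition <- function(x, ...) {
  dvn_flat <- if (nrow(x$dvns)) {
    do.call(rbind, lapply(seq_len(nrow(x$dvns)), function(i) {
      data.frame(copy_id = x$dvns$carriers[[i]],
                 column = x$dvns$column[i],
                 alt_state = x$dvns$alt_state[i],
                 class = "dvn", stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(copy_id = character(0), column = integer(0),
               alt_state = character(0), class = character(0))
  }
  spo_flat <- x$sporadic
  if (nrow(spo_flat)) spo_flat$class <- "sporadic"
  else spo_flat <- data.frame(copy_id = character(0), column = integer(0),
                              alt_state = character(0), class = character(0))
  out <- rbind(dvn_flat, spo_flat)
  out <- out[order(out$column, out$copy_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sporadic mutation rate of an aligned repeat set
#'
#' Percentage of aligned cells carrying a sporadic (singleton) variant:
#' `100 * n_sporadic / (n_copies * n_columns)`. Per-copy rates are also
#' returned because the denominator behind a printed "average" rate is
#' ambiguous in the field's practice.
#'
#' @param partition A `variant_partition`.
#' @param alignment The [array_alignment] it was derived from.
#' @return List with `rate_pct`, and `per_copy_pct` (named vector).
#' @export
sporadic_rate <- function(partition, alignment) {
  n_copies <- partition$n_copies
  n_cols <- ncol(alignment$mat)
  if (n_copies == 0 || n_cols == 0) {
    adom_stop("sporadic rate undefined on an empty alignment", "undefined_rate")
  }
  ids <- setdiff(alignment$copy_ids, alignment$excluded)
  per <- vapply(ids, function(id) sum(partition$sporadic$copy_id == id), numeric(1))
  list(rate_pct = 100 * nrow(partition$sporadic) / (n_copies * n_cols),
       per_copy_pct = 100 * per / n_cols)
}

## ----------------------------------------------------------------- CENP-B

CENPB_CONSENSUS <- "NTTCGNNNNANNCGGGN"
CENPB_ESSENTIAL <- which(strsplit(CENPB_CONSENSUS, "")[[1]] != "N")

#' Scan monomers for the CENP-B box
#'
#' Finds, per monomer, the best match to the 17-bp degenerate CENP-B box
#' consensus `NTTCGNNNNANNCGGGN`, scored at its nine non-N positions, which
#' are essential for CENP-B binding. A box is intact iff all nine essential
#' positions match; monomers whose best window matches at most 5/9 are
#' reported as absent (`present = FALSE`, offset `NA`).
#'
#' @param monomers Character vector (or `seq_records`) of monomer sequences,
#'   each at least 17 bp.
#' @return Data frame: `monomer_index`, `offset` (1-based start of the best
#'   window), `n_essential_matches`, `intact`, `present`.
#' @export
scan_cenpb <- function(monomers) {
  seqs <- as_dna(monomers)
  ess_pos <- CENPB_ESSENTIAL
  ess_base <- chars(CENPB_CONSENSUS)[ess_pos]
  out <- lapply(seq_along(seqs), function(i) {
    s <- chars(seqs[[i]])
    L <- length(s)
    if (L < 17) adom_stop(sprintf("monomer %d shorter than 17 bp", i), "validation")
    best_n <- -1L; best_off <- NA_integer_
    for (off in 1:(L - 16L)) {
      n <- sum(s[off + ess_pos - 1L] == ess_base)
      if (n > best_n) { best_n <- n; best_off <- off }
    }
    present <- best_n > 5L
    data.frame(monomer_index = i,
               offset = if (present) best_off else NA_integer_,
               n_essential_matches = best_n,
               intact = best_n == 9L,
               present = present)
  })
  do.call(rbind, out)
}
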