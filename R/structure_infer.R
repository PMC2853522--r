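## structure_infer: segment ordered HOR copies into homogenisation domains,
## detect barriers, crossover-duplicate pairs and conversion tracts, and
## compare repeat sets (homologues, CENP-A-associated vs bulk) including a
## nearest-neighbour intermingling statistic.

#' Binary DVN carrier matrix (haplotypes)
#'
#' One row per copy (array order), one column per DVN group; entry 1 when the
#' copy carries that group's alternative state. Copies with no DVNs at all are
#' retained as all-zero rows — such copies occur in real clone sets and carry
#' information (they sit at Jaccard similarity 0 to everything).
#'
#' @param partition A `variant_partition`.
#' @param copy_order Character vector of copy ids in array order.
#' @return A `haplotype_matrix` object: `mat` (binary), `dvn_meta` (column
#'   metadata), `empty` flag when there are no DVN groups.
#' @export
haplotype_matrix <- function(partition, copy_order) {
  d <- partition$dvns
  mat <- matrix(0L, nrow = length(copy_order), ncol = nrow(d),
                dimnames = list(copy_order,
                                if (nrow(d)) paste0("c", d$column, d$alt_state) else NULL))
  for (j in seq_len(nrow(d))) {
    carriers <- intersect(d$carriers[[j]], copy_order)
    mat[carriers, j] <- 1L
  }
  structure(list(mat = mat, dvn_meta = d[, c("column", "alt_state", "n_carriers")],
                 empty = nrow(d) == 0),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("<haplotype_matrix> %d copies x %d DVN group(s)%s\n",
              nrow(x$mat), ncol(x$mat), if (x$empty) " [no DVNs]" else ""))
  invisible(x)
}

## Jaccard similarity between binary rows; empty-union pairs score 0, so
## all-zero copies are dissimilar to everything (deliberate: see vignette).
jaccard_rows <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

mean_cross_jaccard <- function(mat, idx_a, idx_b) {
  mean(vapply(idx_a, function(i) {
    mean(vapply(idx_b, function(j) jaccard_rows(mat[i, ], mat[j, ]), numeric(1)))
  }, numeric(1)))
}

#' Segment array-ordered copies into homogenisation domains
#'
#' Adjacency-constrained agglomerative merging on the haplotype matrix:
#' starting from singleton segments, the adjacent pair of segments with the
#' highest mean inter-segment Jaccard similarity is merged repeatedly until
#' the best available merge falls below `tau`. Final segments of two or more
#' copies become domains, each with a defining DVN set (the DVN groups carried
#' by at least half of its members); singleton segments are left unassigned
#' (they are barrier candidates, see [detect_barriers()]).
#'
#' @param hmat A `haplotype_matrix` whose row order is array order.
#' @param tau Merge-stopping similarity threshold (default 0.2).
#' @return A `domain_map` object.
#' @export
segment_domains <- function(hmat, tau = 0.2) {
  mat <- hmat$mat
  n <- nrow(mat)
  if (n == 0) adom_stop("no copies to segment", "empty_input")
  segs <- lapply(seq_len(n), identity)   # list of index vectors, array order
  repeat {
    if (length(segs) == 1) break
    sims <- vapply(seq_len(length(segs) - 1L), function(i) {
      mean_cross_jaccard(mat, segs[[i]], segs[[i + 1]])
    }, numeric(1))
    best <- which.max(sims)
    if (sims[best] < tau) break
    segs[[best]] <- c(segs[[best]], segs[[best + 1]])
    segs[[best + 1]] <- NULL
  }
  is_dom <- vapply(segs, length, integer(1)) >= 2
  doms <- lapply(which(is_dom), function(i) segs[[i]])
  defining <- lapply(doms, function(idx) {
    if (ncol(mat) == 0) return(character(0))
    frac <- colMeans(mat[idx, , drop = FALSE])
    colnames(mat)[frac >= 0.5]
  })
  domains <- if (length(doms)) {
    data.frame(domain = seq_along(doms),
               first_copy = vapply(doms, min, integer(1)),
               last_copy = vapply(doms, max, integer(1)),
               n_copies = vapply(doms, length, integer(1)),
               n_defining_dvns = vapply(defining, length, integer(1)))
  } else {
    data.frame(domain = integer(0), first_copy = integer(0),
               last_copy = integer(0), n_copies = integer(0),
               n_defining_dvns = integer(0))
  }
  structure(
    list(domains = domains, defining = defining,
         unassigned = sort(unlist(segs[!is_dom])) %||% integer(0),
         barriers = data.frame(first_copy = integer(0), last_copy = integer(0),
                               sim_left = numeric(0), sim_right = numeric(0),
                               flank_cross_sim = numeric(0)),
         copy_ids = rownames(mat), tau = tau),
    class = "domain_map"
  )
}

#' @export
print.domain_map <- function(x, ...) {
  cat(sprintf("<domain_map> %d domain(s), %d barrier(s), %d unassigned copy(ies) over %d copies\n",
              nrow(x$domains), nrow(x$barriers), length(x$unassigned),
              length(x$copy_ids)))
  if (nrow(x$domains)) {
    for (i in seq_len(nrow(x$domains))) {
      cat(sprintf("  domain %d: copies %d-%d (%d defining DVNs)\n",
                  i, x$domains$first_copy[i], x$domains$last_copy[i],
                  x$domains$n_defining_dvns[i]))
    }
  }
  invisible(x)
}

#' Domain map as a table
#' @param x A `domain_map`.
#' @param ... Unused.
#' @export
as.data.frame.domain_map <- function(x, ...) {
  rows <- list()
  if (nrow(x$domains)) {
    d <- x$domains
    rows[[1]] <- data.frame(kind = "domain", id = d$domain,
                            first_copy = d$first_copy, last_copy = d$last_copy)
  }
  if (nrow(x$barriers)) {
    rows[[length(rows) + 1]] <- data.frame(kind = "barrier",
                                           id = seq_len(nrow(x$barriers)),
                                           first_copy = x$barriers$first_copy,
                                           last_copy = x$barriers$last_copy)
  }
  if (length(x$unassigned)) {
    rows[[length(rows) + 1]] <- data.frame(kind = "unassigned",
                                           id = seq_along(x$unassigned),
                                           first_copy = x$unassigned,
                                           last_copy = x$unassigned)
  }
  if (!length(rows)) {
    return(data.frame(kind = character(0), id = integer(0),
                      first_copy = integer(0), last_copy = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$first_copy), , drop = FALSE]
}

domain_map_payload <- function(x) {
  list(domains = x$domains, unassigned = x$unassigned, barriers = x$barriers)
}

#' Detect barriers between homogenisation domains
#'
#' A barrier is a run of copies lying between two domains whose mean Jaccard
#' similarity to *both* flanking domains is below `beta` — a short block of
#' copies too diverged from either neighbour to exchange with it. Interior
#' domains and unassigned runs are both candidates (a divergent duplicated
#' pair forms a small domain of its own that still acts as a barrier). The
#' cross-similarity of the flanking domains themselves is reported alongside.
#'
#' @param map A `domain_map` from [segment_domains()].
#' @param hmat The `haplotype_matrix` used to build it.
#' @param beta Maximum similarity to the flanks (default 0.05).
#' @return The map with its `barriers` table filled in.
#' @export
detect_barriers <- function(map, hmat, beta = 0.05) {
  mat <- hmat$mat
  d <- map$domains
  if (nrow(d) < 2) return(map)
  d <- d[order(d$first_copy), , drop = FALSE]
  members <- function(i) d$first_copy[i]:d$last_copy[i]
  bars <- list()
  # Evaluate every interior element (domain or unassigned run) against its
  # nearest flanking domains.
  elements <- c(
    lapply(seq_len(nrow(d)), function(i) list(kind = "domain", idx = members(i))),
    if (length(map$unassigned)) {
      runs <- split(map$unassigned, cumsum(c(1, diff(map$unassigned) != 1)))
      lapply(runs, function(r) list(kind = "unassigned", idx = as.integer(r)))
    }
  )
  starts <- vapply(elements, function(e) min(e$idx), integer(1))
  elements <- elements[order(starts)]
  for (e in elements) {
    lo <- min(e$idx); hi <- max(e$idx)
    left <- d[d$last_copy < lo, , drop = FALSE]
    right <- d[d$first_copy > hi, , drop = FALSE]
    if (!nrow(left) || !nrow(right)) next
    li <- members(which(d$last_copy == max(left$last_copy))[1])
    ri <- members(which(d$first_copy == min(right$first_copy))[1])
    sl <- mean_cross_jaccard(mat, e$idx, li)
    sr <- mean_cross_jaccard(mat, e$idx, ri)
    if (sl < beta && sr < beta) {
      bars[[length(bars) + 1]] <- data.frame(
        first_copy = lo, last_copy = hi, sim_left = sl, sim_right = sr,
        flank_cross_sim = mean_cross_jaccard(mat, li, ri))
    }
  }
  map$barriers <- if (length(bars)) do.call(rbind, bars) else map$barriers
  map
}

#' Detect adjacent near-identical copy pairs (unequal-crossover duplicates)
#'
#' Adjacent copies whose alignment-row identity reaches `min_identity` are
#' reported, annotated with the number of DVN groups private to exactly that
#' pair — the signature of a recent tandem duplication by unequal crossover.
#'
#' @param alignment An array-ordered [array_alignment].
#' @param partition Optional `variant_partition` for private-DVN annotation.
#' @param min_identity Identity threshold (default 0.995).
#' @return Data frame `copy_i`, `copy_j`, `identity`, `n_private_dvns`.
#' @export
detect_duplicate_pairs <- function(alignment, partition = NULL,
                                   min_identity = 0.995) {
  mat <- alignment$mat
  n <- nrow(mat)
  out <- list()
  for (i in seq_len(max(n - 1L, 0L))) {
    ident <- mean(mat[i, ] == mat[i + 1L, ])
    if (ident >= min_identity) {
      priv <- NA_integer_
      if (!is.null(partition)) {
        pair <- sort(c(rownames(mat)[i], rownames(mat)[i + 1L]))
        priv <- sum(vapply(partition$dvns$carriers, function(cs) {
          identical(sort(cs), pair)
        }, logical(1)))
      }
      out[[length(out) + 1]] <- data.frame(
        copy_i = i, copy_j = i + 1L, identity = ident, n_private_dvns = priv)
    }
  }
  if (!length(out)) {
    return(data.frame(copy_i = integer(0), copy_j = integer(0),
                      identity = numeric(0), n_private_dvns = integer(0)))
  }
  do.call(rbind, out)
}

#' Detect cross-domain conversion tracts
#'
#' For a copy assigned to domain D, a conversion tract is a maximal run of at
#' least `k_min` consecutive defining DVN positions of another domain D' (in
#' consensus-column order) at which the copy carries D''s state, uninterrupted
#' by any position where the copy carries one of D's own defining states —
#' the footprint of a gene-conversion event with D' as donor.
#'
#' @param hmat A `haplotype_matrix`.
#' @param map A `domain_map` with at least two domains.
#' @param k_min Minimum run length in DVN positions (default 3).
#' @return Data frame `copy_id`, `copy_index`, `domain`, `donor`,
#'   `col_start`, `col_end`, `n_dvns`.
#' @export
detect_conversion_tracts <- function(hmat, map, k_min = 3L) {
  mat <- hmat$mat
  meta <- hmat$dvn_meta
  d <- map$domains
  empty <- data.frame(copy_id = character(0), copy_index = integer(0),
                      domain = integer(0), donor = integer(0),
                      col_start = integer(0), col_end = integer(0),
                      n_dvns = integer(0))
  if (nrow(d) < 2 || ncol(mat) == 0) return(empty)
  out <- list()
  for (di in seq_len(nrow(d))) {
    own <- map$defining[[di]]
    for (dj in setdiff(seq_len(nrow(d)), di)) {
      donor_def <- setdiff(map$defining[[dj]], own)
      if (!length(donor_def)) next
      # axis: columns defining either domain, in consensus order
      axis_cols <- union(own, donor_def)
      axis_ord <- axis_cols[order(meta$column[match(axis_cols, colnames(mat))])]
      is_donor <- axis_ord %in% donor_def
      for (ci in d$first_copy[di]:d$last_copy[di]) {
        carr <- mat[ci, axis_ord] == 1L
        # state per axis position: +1 donor-state carried, -1 own-state carried
        state <- ifelse(carr & is_donor, 1L, ifelse(carr & !is_donor, -1L, 0L))
        # runs of donor marks, broken by own-state positions (zeros neutral)
        run_len <- 0L; run_start <- NA_integer_; last_mark <- NA_integer_
        flush <- function(pos_end) {
          if (run_len >= k_min) {
            cs <- meta$column[match(axis_ord[run_start], colnames(mat))]
            ce <- meta$column[match(axis_ord[pos_end], colnames(mat))]
            out[[length(out) + 1]] <<- data.frame(
              copy_id = rownames(mat)[ci], copy_index = ci,
              domain = di, donor = dj,
              col_start = cs, col_end = ce, n_dvns = run_len)
          }
        }
        for (p in seq_along(state)) {
          if (state[p] == 1L) {
            if (run_len == 0L) run_start <- p
            run_len <- run_len + 1L
            last_mark <- p
          } else if (state[p] == -1L) {
            if (run_len > 0L) flush(last_mark)
            run_len <- 0L
          }
        }
        if (run_len > 0L) flush(last_mark)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
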