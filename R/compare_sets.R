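## Comparison of two repeat sets (homologues, CENP-A-associated vs bulk):
## joint consensus-anchored alignment, shared/private DVN provenance,
## co-clustering tree, and the nearest-neighbour intermingling statistic.

#' Compare two repeat sets on a joint alignment
#'
#' Both sets are aligned to one joint consensus (unless a prebuilt joint
#' [array_alignment] is supplied), DVNs are recomputed on the joint alignment
#' and classified by carrier provenance: shared (carriers in both sets) or
#' private to one set. An average-linkage co-clustering tree on haplotype
#' Hamming distance is emitted as newick, and the intermingling index with a
#' permutation p-value is computed.
#'
#' @param set_a,set_b Named character vectors / `seq_records` of repeat
#'   copies. Names must be unique across the two sets.
#' @param joint_alignment Optional prebuilt joint [array_alignment] covering
#'   all copies of both sets (rows named as in `set_a`/`set_b`).
#' @param min_share DVN carrier threshold (default 2).
#' @param n_perm Permutations for the intermingling p-value (default 999).
#' @param seed RNG seed for the permutation test.
#' @return A `set_comparison` object: counts `shared`, `private_a`,
#'   `private_b`, `total_dvns`; `newick` tree text; `intermingling` (list
#'   `raw`, `index`, `p_value`); plus the joint `partition` and `alignment`.
#' @export
compare_sets <- function(set_a, set_b, joint_alignment = NULL,
                         min_share = 2L, n_perm = 999L, seed = 1L) {
  a <- as_dna(set_a); b <- as_dna(set_b)
  if (length(a) == 0 || length(b) == 0) {
    adom_stop("both repeat sets must be non-empty", "empty_input")
  }
  if (is.null(names(a)) || anyDuplicated(c(names(a), names(b)))) {
    names(a) <- sprintf("A_%03d", seq_along(a))
    names(b) <- sprintf("B_%03d", seq_along(b))
  }
  ids_a <- names(a); ids_b <- names(b)
  aln <- joint_alignment %||% anchor_align(c(a, b))
  if (!all(c(ids_a, ids_b) %in% aln$copy_ids)) {
    adom_stop("joint alignment does not cover all copies of both sets", "comparison")
  }
  part <- classify_dvns(call_variants(aln), n_copies = nrow(aln$mat),
                        min_share = min_share)
  prov <- vapply(part$dvns$carriers, function(cs) {
    ina <- any(cs %in% ids_a); inb <- any(cs %in% ids_b)
    if (ina && inb) "shared" else if (ina) "private_a" else "private_b"
  }, character(1))
  hm <- haplotype_matrix(part, c(ids_a, ids_b))
  ha <- hm$mat[ids_a, , drop = FALSE]
  hb <- hm$mat[ids_b, , drop = FALSE]
  nwk <- haplotype_tree(hm$mat)
  inter <- intermingling_index(ha, hb, n_perm = n_perm, seed = seed)
  structure(
    list(shared = sum(prov == "shared"),
         private_a = sum(prov == "private_a"),
         private_b = sum(prov == "private_b"),
         total_dvns = nrow(part$dvns),
         dvn_provenance = prov,
         newick = nwk,
         intermingling = inter,
         partition = part,
         alignment = aln,
         ids_a = ids_a, ids_b = ids_b),
    class = "set_comparison"
  )
}

#' @export
print.set_comparison <- function(x, ...) {
  cat(sprintf("<set_comparison> %d DVN group(s): %d shared, %d private to A, %d private to B\n",
              x$total_dvns, x$shared, x$private_a, x$private_b))
  cat(sprintf("  intermingling index %.3f (raw %.3f, p = %.4g)\n",
              x$intermingling$index, x$intermingling$raw, x$intermingling$p_value))
  invisible(x)
}

## Average-linkage tree on haplotype Hamming distance, as newick text.
haplotype_tree <- function(mat) {
  if (nrow(mat) < 3) return(NA_character_)
  d <- as.dist(hamming_matrix(mat))
  hc <- hclust(d, method = "average")
  ape::write.tree(ape::as.phylo(hc))
}

hamming_matrix <- function(mat) {
  n <- nrow(mat)
  dm <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (ncol(mat)) {
    # |x - y|_1 on binary rows = Hamming distance
    g <- mat %*% t(mat)
    rs <- rowSums(mat)
    dm <- outer(rs, rs, "+") - 2 * g
  }
  dm
}

#' Nearest-neighbour intermingling of two repeat sets
#'
#' Raw statistic: the fraction of repeats whose nearest non-self neighbour in
#' haplotype Hamming distance belongs to the other set, with ties contributing
#' fractionally (a repeat with t co-minimal neighbours, o of them in the other
#' set, contributes o/t). The index normalises the raw statistic by its
#' expectation under random labels (for a member of A, |B| / (|A|+|B|-1)), so
#' fully mixed sets score ~1 and fully separated sets score 0. The p-value is
#' an upper-tail label-permutation test (more intermingled than random).
#'
#' @param mat_a,mat_b Binary haplotype matrices (rows = copies) sharing one
#'   DVN column space.
#' @param n_perm Number of label permutations (default 999).
#' @param seed RNG seed.
#' @return List `raw`, `index`, `expected`, `p_value`.
#' @export
intermingling_index <- function(mat_a, mat_b, n_perm = 999L, seed = 1L) {
  na <- nrow(mat_a); nb <- nrow(mat_b)
  if (na == 0 || nb == 0) {
    adom_stop("intermingling undefined: one of the sets is empty", "undefined")
  }
  if (ncol(mat_a) != ncol(mat_b)) {
    adom_stop("haplotype matrices do not share a DVN coordinate space", "comparison")
  }
  all_mat <- rbind(mat_a, mat_b)
  n <- na + nb
  dm <- hamming_matrix(all_mat)
  diag(dm) <- Inf
  labels <- c(rep(TRUE, na), rep(FALSE, nb))   # TRUE = set A
  raw_stat <- function(lab) {
    contrib <- vapply(seq_len(n), function(i) {
      m <- min(dm[i, ])
      ties <- which(dm[i, ] == m)
      mean(lab[ties] != lab[i])
    }, numeric(1))
    mean(contrib)
  }
  raw <- raw_stat(labels)
  expected <- 2 * na * nb / (n * (n - 1))
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(r) raw_stat(sample(labels)), numeric(1))
  })
  list(raw = raw, index = raw / expected, expected = expected,
       p_value = (1 + sum(perm >= raw)) / (n_perm + 1))
}
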