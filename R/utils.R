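## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

adom_stop <- function(msg, class) {
  stop(structure(
    class = c(paste0("alphadom_", class), "alphadom_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Fraction identity between two DNA sequences
#'
#' Equal-length sequences are compared position-wise (Hamming identity);
#' unequal lengths fall back to a global pairwise alignment with the package's
#' default scoring (match +1, mismatch -1, gap open 4, gap extend 1).
#'
#' @param a,b DNA strings.
#' @return Identity as a fraction in \[0, 1\].
#' @export
seq_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    ca <- chars(a); cb <- chars(b)
    return(mean(ca == cb))
  }
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = .submat(), gapOpening = 4, gapExtension = 1
  )
  Biostrings::pid(pa) / 100
}

.submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE
      )
    }
    m
  }
})

## Run code with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Random DNA string of length n from the ambient RNG.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Substitute a fraction `rate` of positions with a different base (ambient RNG).
mutate_seq <- function(seq, rate) {
  x <- chars(seq)
  n <- length(x)
  k <- rpois(1, rate * n)
  if (k == 0) return(seq)
  pos <- sample.int(n, min(k, n))
  for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
  paste(x, collapse = "")
}

## Complement of a set of closed intervals within [1, len].
interval_complement <- function(starts, ends, len) {
  if (length(starts) == 0) {
    return(data.frame(start = 1L, end = as.integer(len)))
  }
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  gs <- integer(0); ge <- integer(0)
  cur <- 1L
  for (i in seq_along(starts)) {
    if (starts[i] > cur) {
      gs <- c(gs, cur); ge <- c(ge, starts[i] - 1L)
    }
    cur <- max(cur, ends[i] + 1L)
  }
  if (cur <= len) {
    gs <- c(gs, cur); ge <- c(ge, as.integer(len))
  }
  data.frame(start = as.integer(gs), end = as.integer(ge))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Mean pairwise identity among copies, subsampling pairs for large sets.
mean_pairwise_identity <- function(copies, max_pairs = 200L) {
  n <- length(copies)
  if (n < 2) return(NA_real_)
  pairs <- t(utils::combn(n, 2))
  if (nrow(pairs) > max_pairs) {
    pairs <- pairs[seq(1, nrow(pairs), length.out = max_pairs), , drop = FALSE]
  }
  mean(vapply(
    seq_len(nrow(pairs)),
    function(r) seq_identity(copies[pairs[r, 1]], copies[pairs[r, 2]]),
    numeric(1)
  ))
}
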