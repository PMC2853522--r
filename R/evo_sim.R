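## evo_sim: forward-time simulator of a tandem HOR array evolving under
## sporadic point mutation, gene conversion, and similarity-gated unequal
## crossover, with a replayable ground-truth event log. One chromosome
## lineage is followed: after an unequal crossover a fair coin decides which
## reciprocal product (expansion or contraction) is transmitted.

#' Simulation parameters
#'
#' Defaults describe a homogeneous pericentromeric HOR array: 55 copies of a
#' 1866-bp unit, sporadic substitution pressure tuned so that ~0.2% per-base
#' divergence accumulates over the default run, occasional conversion tracts,
#' and unequal crossovers gated to near-identical, linearly close partners
#' (mitotic exchanges only happen between repeats in close vicinity, which
#' are therefore almost identical in sequence).
#'
#' @param n0 Initial copy number.
#' @param unit_len Unit length in bp.
#' @param mu Substitutions per bp per copy per generation.
#' @param conv_rate Conversion events per array per generation.
#' @param conv_tract_mean Mean conversion tract length, bp (geometric).
#' @param xo_rate Unequal-crossover attempts per array per generation.
#' @param xo_identity_min Minimum full-unit identity between the two partners
#'   for a crossover to succeed (the similarity gate).
#' @param xo_offset_max Maximum misalignment offset, in copies, for both
#'   conversion donors and crossover partners.
#' @param copy_bounds Length-2 integer vector; events that would push the
#'   copy number outside these bounds are rejected (and logged as such).
#' @param generations Number of generations for [evolve()].
#' @param seed Integer seed; every randomised output is a deterministic
#'   function of the parameter set including this seed.
#' @return A `sim_params` object.
#' @export
sim_params <- function(n0 = 55L, unit_len = 1866L, mu = 2e-5,
                       conv_rate = 0.5, conv_tract_mean = 300,
                       xo_rate = 0.2, xo_identity_min = 0.98,
                       xo_offset_max = 5L, copy_bounds = c(5L, 200L),
                       generations = 100L, seed = 1L) {
  p <- list(n0 = as.integer(n0), unit_len = as.integer(unit_len), mu = mu,
            conv_rate = conv_rate, conv_tract_mean = conv_tract_mean,
            xo_rate = xo_rate, xo_identity_min = xo_identity_min,
            xo_offset_max = as.integer(xo_offset_max),
            copy_bounds = as.integer(copy_bounds),
            generations = as.integer(generations), seed = as.integer(seed))
  if (any(c(p$mu, p$conv_rate, p$xo_rate) < 0)) {
    adom_stop("rates must be non-negative", "parameter")
  }
  if (p$xo_identity_min <= 0 || p$xo_identity_min > 1) {
    adom_stop("xo_identity_min must be in (0, 1]", "parameter")
  }
  if (p$seed >= 2^31 - 10 || p$seed < 0) {
    adom_stop("seed must be a non-negative integer below 2^31 - 10", "parameter")
  }
  structure(p, class = "sim_params")
}

#' Initialise a simulated array
#'
#' `n0` identical copies of a random (seeded) `unit_len` sequence, or of a
#' user-supplied ancestor — the state of an array immediately after complete
#' homogenisation.
#'
#' @param params A `sim_params` object.
#' @param ancestor Optional ancestor unit sequence of length `unit_len`.
#' @return A `sim_array`: list `copies`, `generation`, `lineage`, `ancestor`.
#' @export
init_array <- function(params, ancestor = NULL) {
  if (params$n0 < params$copy_bounds[1] || params$n0 > params$copy_bounds[2]) {
    adom_stop("n0 outside copy_bounds", "parameter")
  }
  if (is.null(ancestor)) {
    ancestor <- with_seed(params$seed, random_dna(params$unit_len))
  } else if (nchar(ancestor) != params$unit_len) {
    adom_stop("ancestor length does not match unit_len", "parameter")
  }
  structure(list(copies = rep(ancestor, params$n0), generation = 0L,
                 lineage = "L0", ancestor = ancestor),
            class = "sim_array")
}

#' @export
print.sim_array <- function(x, ...) {
  cat(sprintf("<sim_array> %d copies of ~%d bp, generation %d, lineage %s\n",
              length(x$copies), nchar(x$copies[1]), x$generation, x$lineage))
  invisible(x)
}

## One generation, consuming the ambient RNG. Returns list(array, events).
## Event order is fixed (mutation -> conversion -> crossover) so that replay
## is deterministic.
step_generation <- function(array, params) {
  copies <- array$copies
  gen <- array$generation + 1L
  events <- list()
  log_ev <- function(...) events[[length(events) + 1L]] <<- list(gen = gen, ...)

  # (1) sporadic substitutions
  for (ci in seq_along(copies)) {
    len <- nchar(copies[ci])
    nmut <- rpois(1, params$mu * len)
    if (nmut > 0) {
      x <- chars(copies[ci])
      for (m in seq_len(nmut)) {
        pos <- sample.int(len, 1)
        from <- x[pos]
        to <- sample(setdiff(c("A", "C", "G", "T"), from), 1)
        x[pos] <- to
        log_ev(type = "mutation", copy = ci, pos = pos, from = from, to = to)
      }
      copies[ci] <- paste(x, collapse = "")
    }
  }

  # (2) gene conversions: copy-number neutral, donor within +/- xo_offset_max
  ncv <- rpois(1, params$conv_rate)
  for (e in seq_len(ncv)) {
    n <- length(copies)
    acceptor <- sample.int(n, 1)
    cand <- setdiff(
      intersect((acceptor - params$xo_offset_max):(acceptor + params$xo_offset_max),
                seq_len(n)),
      acceptor)
    if (!length(cand)) next
    donor <- if (length(cand) == 1) cand else sample(cand, 1)
    tract <- rgeom(1, 1 / params$conv_tract_mean) + 1L
    len <- min(nchar(copies[acceptor]), nchar(copies[donor]))
    start <- sample.int(len, 1)
    end <- min(len, start + tract - 1L)
    substr(copies[acceptor], start, end) <- substr(copies[donor], start, end)
    log_ev(type = "conversion", donor = donor, acceptor = acceptor,
           start = start, end = end)
  }

  # (3) unequal crossovers: similarity-gated, one reciprocal product kept
  nxo <- rpois(1, params$xo_rate)
  for (e in seq_len(nxo)) {
    n <- length(copies)
    i <- sample.int(n, 1)
    d <- sample.int(params$xo_offset_max, 1)
    if (i + d > n) {
      log_ev(type = "crossover_rejected", i = i, offset = d, reason = "range")
      next
    }
    ident <- seq_identity(copies[i], copies[i + d])
    if (ident < params$xo_identity_min) {
      log_ev(type = "crossover_rejected", i = i, offset = d, reason = "identity_gate")
      next
    }
    expand <- runif(1) < 0.5
    new_n <- if (expand) n + d else n - d
    if (new_n < params$copy_bounds[1] || new_n > params$copy_bounds[2]) {
      log_ev(type = "crossover_rejected", i = i, offset = d, reason = "copy_bounds")
      next
    }
    copies <- if (expand) {
      c(copies[1:(i + d)], copies[(i + 1):n])
    } else {
      c(copies[1:i], if (i + d < n) copies[(i + d + 1):n])
    }
    log_ev(type = "crossover", i = i, offset = d,
           kept_product = if (expand) "expansion" else "contraction",
           copy_number_change = new_n - n)
  }

  array$copies <- copies
  array$generation <- gen
  list(array = array, events = events)
}

#' Advance a simulated array by one generation
#'
#' Applies, in order: Poisson(mu x unit length) substitutions per copy at
#' uniform positions; Poisson(conv_rate) conversions overwriting a geometric
#' tract of the acceptor with donor sequence (copy-number neutral); and
#' Poisson(xo_rate) unequal-crossover attempts between copy i and copy i+d,
#' accepted only when the two copies' identity reaches the similarity gate,
#' whereupon a fair coin keeps the expansion or contraction product. Failed
#' attempts are logged as rejected. Consumes the ambient RNG; [evolve()]
#' seeds it from the parameters.
#'
#' @param array A `sim_array`.
#' @param params A `sim_params`.
#' @return List with `array` and `events` (list of event records).
#' @export
sim_step <- function(array, params) step_generation(array, params)

#' Evolve an array for the configured number of generations
#'
#' Deterministic in the parameter set: the RNG is seeded from `params$seed`
#' at entry. The returned event log replays to the final array bit-exactly
#' (see [replay_log()]).
#'
#' @param array A `sim_array` from [init_array()].
#' @param params A `sim_params`.
#' @param generations Override for `params$generations`.
#' @return List `array` (final state) and `log` (an `event_log`).
#' @export
evolve <- function(array, params, generations = NULL) {
  gens <- generations %||% params$generations
  initial <- array
  events <- list()
  with_seed(params$seed + 1L, {
    for (g in seq_len(gens)) {
      st <- step_generation(array, params)
      array <- st$array
      events <- c(events, st$events)
    }
  })
  list(array = array,
       log = structure(list(events = events, initial = initial),
                       class = "event_log"))
}

#' @export
print.event_log <- function(x, ...) {
  types <- vapply(x$events, function(e) e$type, character(1))
  cat(sprintf("<event_log> %d event(s): %s\n", length(x$events),
              paste(sprintf("%s=%d", names(table(types)), table(types)),
                    collapse = ", ")))
  invisible(x)
}

#' Replay an event log against its initial array
#'
#' Applies the logged mutations, conversions, and crossovers in order to the
#' initial array. Replay is exact: the result reproduces the simulated final
#' array bit-for-bit, which is the correctness contract of the logger.
#'
#' @param log An `event_log` from [evolve()].
#' @param initial Optional starting `sim_array` (defaults to the one stored
#'   in the log).
#' @return The reconstructed `sim_array`.
#' @export
replay_log <- function(log, initial = NULL) {
  array <- initial %||% log$initial
  copies <- array$copies
  gen <- array$generation
  for (e in log$events) {
    gen <- max(gen, e$gen)
    switch(e$type,
      mutation = {
        substr(copies[e$copy], e$pos, e$pos) <- e$to
      },
      conversion = {
        substr(copies[e$acceptor], e$start, e$end) <-
          substr(copies[e$donor], e$start, e$end)
      },
      crossover = {
        n <- length(copies)
        copies <- if (e$kept_product == "expansion") {
          c(copies[1:(e$i + e$offset)], copies[(e$i + 1):n])
        } else {
          c(copies[1:e$i], if (e$i + e$offset < n) copies[(e$i + e$offset + 1):n])
        }
      },
      crossover_rejected = NULL
    )
  }
  array$copies <- copies
  array$generation <- gen
  array
}

#' Split an array into two independently evolving lineages
#'
#' Models homologues separated long ago and now evolving independently: two
#' copies of the array are evolved `g_split` further generations each, with
#' independent RNG substreams derived from the master seed.
#'
#' @param array A `sim_array`.
#' @param params A `sim_params` (its `seed` is the master seed).
#' @param g_split Generations of independent evolution after the split.
#' @return List of two `sim_array`s (lineages "A" and "B") with their logs.
#' @export
split_lineages <- function(array, params, g_split) {
  seeds <- with_seed(params$seed + 2L, sample.int(2^31 - 10, 2))
  pa <- params; pa$seed <- seeds[1]
  pb <- params; pb$seed <- seeds[2]
  arr_a <- array; arr_a$lineage <- paste0(array$lineage, ".A")
  arr_b <- array; arr_b$lineage <- paste0(array$lineage, ".B")
  if (g_split == 0) return(list(a = arr_a, b = arr_b, log_a = NULL, log_b = NULL))
  ra <- evolve(arr_a, pa, generations = g_split)
  rb <- evolve(arr_b, pb, generations = g_split)
  list(a = ra$array, b = rb$array, log_a = ra$log, log_b = rb$log)
}

#' Sample cloned repeats from an array (PCR-clone emulation)
#'
#' Draws `n` copies uniformly with replacement; with probability `dup_prob` a
#' draw re-uses the previous draw's template (a PCR duplicate). Sequences are
#' truncated to `window` (a sub-interval of the unit, e.g. the ~730 bp a
#' primer pair can reach), and array positions are deliberately absent from
#' the output ids: cloned repeats are anonymous, exactly as in real clone
#' sets where the relative positions of the repeats are unknown.
#'
#' @param array A `sim_array`.
#' @param n Number of clones.
#' @param window Length-2 vector, 1-based closed interval within the unit.
#' @param dup_prob Probability of re-using the previous template.
#' @param seed RNG seed.
#' @return A `seq_records` data frame of anonymous clones.
#' @export
sample_clones <- function(array, n, window = NULL, dup_prob = 0, seed = 1L) {
  if (n < 1) adom_stop("n must be >= 1", "parameter")
  unit_len <- min(nchar(array$copies))
  window <- window %||% c(1L, unit_len)
  if (window[2] > max(nchar(array$copies)) || window[1] < 1) {
    adom_stop("window outside the unit", "parameter")
  }
  idx <- with_seed(seed, {
    out <- integer(n)
    out[1] <- sample.int(length(array$copies), 1)
    for (t in seq_len(n - 1L) + 1L) {
      out[t] <- if (runif(1) < dup_prob) out[t - 1L]
                else sample.int(length(array$copies), 1)
    }
    out
  })
  seqs <- substr(array$copies[idx], window[1], window[2])
  new_seq_records(sprintf("clone_%03d", seq_len(n)), seqs,
                  sprintf("synthetic clone sample (lineage %s)", array$lineage))
}
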