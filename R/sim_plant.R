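## Planted-truth generators. Unlike the forward simulator (evo_sim.R), these
## construct arrays with *known* DVNs, domain boundaries, conversion tracts
## and duplicate pairs, so recovery tests can score the pipeline exactly.
## All randomness is a deterministic function of `seed`.

## Substitute exactly n_sub random positions (never touching `protect`).
mutate_fixed <- function(seq, n_sub, protect = integer(0)) {
  x <- chars(seq)
  pool <- setdiff(seq_along(x), protect)
  pos <- sample(pool, min(n_sub, length(pool)))
  for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
  paste(x, collapse = "")
}

## Carrier draw: each of `members` independently with prob `frac`, clamped to
## [min_carriers, max_carriers].
draw_carriers <- function(members, frac, min_carriers = 2L,
                          max_carriers = length(members)) {
  hit <- members[runif(length(members)) < frac]
  if (length(hit) < min_carriers) {
    hit <- sample(members, min_carriers)
  } else if (length(hit) > max_carriers) {
    hit <- sample(hit, max_carriers)
  }
  sort(hit)
}

#' Plant a multi-domain array with known DVNs and sporadic mutations
#'
#' Builds `sum(n_copies)` copies of a random ancestor, organised into
#' consecutive homogenisation domains with disjoint planted DVN sets: each
#' domain owns `n_dvns[d]` columns, and each domain member carries each of
#' them independently with probability `carrier_frac` (at least 2 carriers
#' per DVN — the definition of a DVN — and never a majority of all copies,
#' so the consensus stays ancestral). Sporadic mutations are planted as true
#' singletons at distinct free columns. Substitutions only, so all copies
#' share one length.
#'
#' @param n_copies Integer vector: copies per domain (default `c(20, 20)`).
#' @param unit_len Copy length in bp (default 400).
#' @param n_dvns DVN columns per domain (default 12 each).
#' @param carrier_frac Per-member carrier probability (default 0.8). Carriers
#'   of any single DVN are additionally capped at 42% of all copies, so the
#'   ancestral state keeps an absolute consensus majority even after
#'   conversion recipients are planted on top.
#' @param sporadic Per-base sporadic mutation probability (default 0.002).
#' @param seed RNG seed.
#' @param ancestor Optional ancestor sequence.
#' @param protect Columns excluded from DVN and sporadic planting (e.g. a
#'   restriction site or protein-binding box that the array conserves).
#' @return List: `copies` (named, array order), `domain_of`, `boundaries`
#'   (last copy index of each domain), `dvns` (column, alt_state, domain,
#'   carriers), `sporadic` (copy, column, alt_state), `ancestor`.
#' @export
plant_domain_array <- function(n_copies = c(20L, 20L), unit_len = 400L,
                               n_dvns = rep(12L, length(n_copies)),
                               carrier_frac = 0.8, sporadic = 0.002,
                               seed = 1L, ancestor = NULL,
                               protect = integer(0)) {
  stopifnot(length(n_dvns) == length(n_copies))
  with_seed(seed, {
    total <- sum(n_copies)
    if (is.null(ancestor)) ancestor <- random_dna(unit_len)
    anc <- chars(ancestor)
    domain_of <- rep(seq_along(n_copies), n_copies)
    members <- split(seq_len(total), domain_of)
    n_spor <- round(sporadic * total * unit_len)
    cols <- sample(setdiff(seq_len(unit_len), protect), sum(n_dvns) + n_spor)
    dvn_cols <- cols[seq_len(sum(n_dvns))]
    spor_cols <- cols[-seq_len(sum(n_dvns))]
    dom_of_col <- rep(seq_along(n_dvns), n_dvns)
    max_carr <- max(2L, floor(0.42 * total))
    dvns <- data.frame(column = dvn_cols,
                       alt_state = vapply(dvn_cols, function(c)
                         sample(setdiff(c("A", "C", "G", "T"), anc[c]), 1),
                         character(1)),
                       domain = dom_of_col, stringsAsFactors = FALSE)
    dvns$carriers <- lapply(seq_len(nrow(dvns)), function(i) {
      draw_carriers(members[[dvns$domain[i]]], carrier_frac,
                    max_carriers = min(length(members[[dvns$domain[i]]]), max_carr))
    })
    spor <- data.frame(copy = sample.int(total, n_spor, replace = TRUE),
                       column = spor_cols,
                       stringsAsFactors = FALSE)
    spor$alt_state <- vapply(spor$column, function(c)
      sample(setdiff(c("A", "C", "G", "T"), anc[c]), 1), character(1))

    mat <- matrix(rep(anc, total), nrow = total, byrow = TRUE)
    for (i in seq_len(nrow(dvns))) {
      mat[dvns$carriers[[i]], dvns$column[i]] <- dvns$alt_state[i]
    }
    for (i in seq_len(nrow(spor))) {
      mat[spor$copy[i], spor$column[i]] <- spor$alt_state[i]
    }
    copies <- setNames(apply(mat, 1, paste, collapse = ""),
                       sprintf("copy_%03d", seq_len(total)))
    dvns <- dvns[order(dvns$column), , drop = FALSE]
    rownames(dvns) <- NULL
    list(copies = copies, domain_of = domain_of,
         boundaries = cumsum(n_copies), dvns = dvns, sporadic = spor,
         ancestor = ancestor)
  })
}

#' Plant gene-conversion tracts onto a planted-domain array
#'
#' Overwrites, in each chosen recipient copy of domain `recipient_domain`, a
#' run of `tract_dvns` consecutive donor-domain DVN columns with the donor
#' state: inside the spanned column interval the recipient carries the donor
#' DVNs and loses its own domain's states — the footprint of a conversion
#' event. Planted sporadic mutations inside the tract are wiped (and removed
#' from the truth table).
#'
#' @param planted Output of [plant_domain_array()].
#' @param n_tracts Number of recipient copies (one tract each).
#' @param tract_dvns Donor DVNs per tract (default 5).
#' @param recipient_domain,donor_domain Domain indices (defaults 1 and 2).
#' @param seed RNG seed.
#' @return `planted`, with modified `copies`, adjusted `sporadic`, and a
#'   `tracts` truth table (copy, donor, col_start, col_end, n_dvns).
#' @export
plant_conversion <- function(planted, n_tracts = 1L, tract_dvns = 5L,
                             recipient_domain = 1L, donor_domain = 2L,
                             seed = 1L) {
  with_seed(seed, {
    anc <- chars(planted$ancestor)
    d <- planted$dvns
    donor_rows <- which(d$domain == donor_domain)
    donor_rows <- donor_rows[order(d$column[donor_rows])]
    if (length(donor_rows) < tract_dvns) {
      adom_stop("donor domain has fewer DVN columns than tract_dvns", "parameter")
    }
    members <- which(planted$domain_of == recipient_domain)
    recipients <- sample(members, n_tracts)
    tracts <- list()
    for (r in recipients) {
      s <- sample.int(length(donor_rows) - tract_dvns + 1L, 1)
      run <- donor_rows[s:(s + tract_dvns - 1L)]
      col_start <- d$column[run[1]]
      col_end <- d$column[run[length(run)]]
      x <- chars(planted$copies[r])
      # donor's sequence over the interval: ancestral except donor DVN alts
      x[col_start:col_end] <- anc[col_start:col_end]
      x[d$column[run]] <- d$alt_state[run]
      planted$copies[r] <- paste(x, collapse = "")
      drop <- planted$sporadic$copy == r &
        planted$sporadic$column >= col_start & planted$sporadic$column <= col_end
      planted$sporadic <- planted$sporadic[!drop, , drop = FALSE]
      tracts[[length(tracts) + 1]] <- data.frame(
        copy = r, donor = donor_domain, col_start = col_start,
        col_end = col_end, n_dvns = tract_dvns)
    }
    planted$tracts <- do.call(rbind, tracts)
    planted
  })
}

CENPB_BOX_EXAMPLE <- "ATTCGTTGGAAACGGGA"
HINDIII_SITE <- "AAGCTT"

## Remove unwanted occurrences of `site` from `seq` by substituting the third
## base of each occurrence outside `keep_at` (1-based starts to preserve).
scrub_site <- function(seq, site, keep_at = integer(0)) {
  repeat {
    occ <- Biostrings::start(Biostrings::matchPattern(site, seq))
    occ <- setdiff(occ, keep_at)
    if (!length(occ)) return(seq)
    p <- occ[1] + 2L
    old <- substr(seq, p, p)
    substr(seq, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
}

#' Synthetic archetype of a highly homogeneous pericentromeric HOR array
#'
#' Generates, entirely in code, an array with the canonical structure of the
#' best-characterised pericentromeric alpha-satellite locus: a homogeneous
#' core of 55 tandem 1866-bp HOR units (11 diverged ~170-bp monomers each,
#' one HindIII site and one CENP-B box per unit), 281 planted DVN columns
#' organised into two large domains (copies 1-30 and 36-55) separated by an
#' intermediate block (copies 31-35) containing a near-identical adjacent
#' pair (32, 33) with pair-private DVNs, ~0.2% planted sporadic singletons,
#' and divergent flanking alphoid DNA padding the record to 141,084 bp.
#'
#' Structural constants (55/11/1866/281/0.2%, domain split 30/5/20, the
#' duplicate pair) are fixed study conditions, not tunables; the seed only
#' moves the random sequence content around them.
#'
#' @param seed RNG seed.
#' @param n_dvns Named DVN-column budget: `s1`, `s2` (large domains), `s3`
#'   (intermediate block), `pair` (private to the duplicate pair). Must total
#'   281 by default.
#' @param carrier_frac Carrier probabilities for s1/s2 and s3 DVNs.
#' @param sporadic_rate Planted per-base sporadic singleton rate.
#' @param flank_divergence Per-base divergence of flanking units.
#' @param family_divergence Divergence of each monomer family from the base
#'   monomer.
#' @return List: `record` (one-row `seq_records` of the full array),
#'   `monomer_consensus` (the base monomer), `site`, truth tables (`dvns`,
#'   `sporadic`, `domains`, `pair`, `copies`, `ancestor_unit`), and layout
#'   (`core_start`, `core_len`, `unit_len`, `k`, `n_core`).
#' @export
sim_archetype_array <- function(seed = 1L,
                                n_dvns = c(s1 = 110L, s2 = 110L, s3 = 45L,
                                           pair = 16L),
                                carrier_frac = c(s12 = 0.6, s3 = 0.8),
                                sporadic_rate = 0.002,
                                flank_divergence = 0.10,
                                family_divergence = 0.15) {
  total_length <- 141084L
  n_core <- 55L
  k <- 11L
  mono_lens <- c(170L, 170L, 169L, 170L, 169L, 170L, 170L, 169L, 170L, 169L, 170L)
  unit_len <- sum(mono_lens)  # 1866
  site_at <- 61L              # within monomer family 1
  box_at <- 131L
  with_seed(seed, {
    base <- random_dna(170L)
    substr(base, site_at, site_at + 5L) <- HINDIII_SITE
    substr(base, box_at, box_at + 16L) <- CENPB_BOX_EXAMPLE
    base <- scrub_site(base, HINDIII_SITE, keep_at = site_at)
    protect1 <- c(site_at:(site_at + 5L), box_at:(box_at + 16L))
    families <- vapply(seq_len(k), function(f) {
      fam <- substr(base, 1L, mono_lens[f])
      fam <- mutate_fixed(fam, round(family_divergence * mono_lens[f]),
                          protect = if (f == 1) protect1 else integer(0))
      scrub_site(fam, HINDIII_SITE, keep_at = if (f == 1) site_at else integer(0))
    }, character(1))
    ancestor <- paste(families, collapse = "")
    ancestor <- scrub_site(ancestor, HINDIII_SITE, keep_at = site_at)
    anc <- chars(ancestor)

    ## --- plant 281 DVN columns + sporadic singletons -----------------------
    edge_protect <- c(1:8, (unit_len - 7L):unit_len)
    allowed <- setdiff(seq_len(unit_len), c(protect1, edge_protect))
    n_spor <- round(sporadic_rate * n_core * unit_len)
    cols <- sample(allowed, sum(n_dvns) + n_spor)
    idx <- split(seq_len(sum(n_dvns)), rep(names(n_dvns), n_dvns))
    spor_cols <- cols[-seq_len(sum(n_dvns))]

    s1_members <- 1:30; s3_members <- 31:35; s2_members <- 36:55
    max_carr <- 27L   # always a minority of the 55 copies
    mk_dvns <- function(colv, subset, members, frac, tie = NULL) {
      data.frame(column = colv,
                 alt_state = vapply(colv, function(c)
                   sample(setdiff(c("A", "C", "G", "T"), anc[c]), 1), character(1)),
                 subset = subset,
                 carriers = I(lapply(colv, function(c) {
                   if (!is.null(tie)) {
                     pool <- c(setdiff(members, tie), "dup")
                     hit <- pool[runif(length(pool)) < frac]
                     hit <- unique(c(hit, if (length(hit) < 1) sample(pool, 1)))
                     out <- sort(as.integer(c(setdiff(hit, "dup"),
                                              if ("dup" %in% hit) tie)))
                     if (length(out) < 2) out <- sort(c(out, tie))
                     unique(out)
                   } else {
                     draw_carriers(members, frac, max_carriers = max_carr)
                   }
                 })),
                 stringsAsFactors = FALSE)
    }
    d_s1 <- mk_dvns(cols[idx$s1], "s1", s1_members, carrier_frac[["s12"]])
    d_s2 <- mk_dvns(cols[idx$s2], "s2", s2_members, carrier_frac[["s12"]])
    d_s3 <- mk_dvns(cols[idx$s3], "s3", s3_members, carrier_frac[["s3"]],
                    tie = c(32L, 33L))
    d_pair <- data.frame(column = cols[idx$pair],
                         alt_state = vapply(cols[idx$pair], function(c)
                           sample(setdiff(c("A", "C", "G", "T"), anc[c]), 1),
                           character(1)),
                         subset = "pair",
                         carriers = I(rep(list(c(32L, 33L)), n_dvns[["pair"]])),
                         stringsAsFactors = FALSE)
    dvns <- rbind(d_s1, d_s2, d_s3, d_pair)

    ## three s1 DVNs become shared deletions ('-'), at columns whose
    ## neighbours differ from them so the gap placement in a pairwise
    ## alignment is unambiguous; rare carriers keep unit lengths modal.
    ok_del <- which(dvns$subset == "s1" &
                    vapply(dvns$column, function(c)
                      anc[c - 1] != anc[c] && anc[c] != anc[c + 1], logical(1)))
    del_rows <- head(ok_del, 3L)
    dvns$alt_state[del_rows] <- "-"
    for (r in del_rows) dvns$carriers[[r]] <- sort(sample(s1_members, 3L))

    spor <- data.frame(copy = sample.int(n_core, n_spor, replace = TRUE),
                       column = spor_cols, stringsAsFactors = FALSE)
    ## the duplicate pair stays near-identical: at most 2 singletons each
    for (cp in c(32L, 33L)) {
      excess <- which(spor$copy == cp)
      if (length(excess) > 2) {
        move <- excess[-(1:2)]
        spor$copy[move] <- sample(setdiff(seq_len(n_core), c(32L, 33L)),
                                  length(move), replace = TRUE)
      }
    }
    spor$alt_state <- vapply(spor$column, function(c)
      sample(setdiff(c("A", "C", "G", "T"), anc[c]), 1), character(1))

    ## --- build the 55 core copies ------------------------------------------
    mat <- matrix(rep(anc, n_core), nrow = n_core, byrow = TRUE)
    dels <- vector("list", n_core)
    for (i in seq_len(nrow(dvns))) {
      if (dvns$alt_state[i] == "-") {
        for (cp in dvns$carriers[[i]]) {
          dels[[cp]] <- c(dels[[cp]], dvns$column[i])
        }
      } else {
        mat[dvns$carriers[[i]], dvns$column[i]] <- dvns$alt_state[i]
      }
    }
    for (i in seq_len(nrow(spor))) {
      mat[spor$copy[i], spor$column[i]] <- spor$alt_state[i]
    }
    copies <- vapply(seq_len(n_core), function(cp) {
      x <- mat[cp, ]
      if (length(dels[[cp]])) x <- x[-dels[[cp]]]
      paste(x, collapse = "")
    }, character(1))
    names(copies) <- sprintf("copy_%02d", seq_len(n_core))
    core <- paste(copies, collapse = "")

    ## --- divergent flanks, padding to the full record length ---------------
    flank_units <- function(n) {
      paste(vapply(seq_len(n), function(i)
        mutate_fixed(ancestor, round(flank_divergence * unit_len)),
        character(1)), collapse = "")
    }
    core_len <- nchar(core)
    left_len <- (total_length - core_len) %/% 2L
    right_len <- total_length - core_len - left_len
    left_raw <- flank_units(ceiling(left_len / unit_len) + 1L)
    right_raw <- flank_units(ceiling(right_len / unit_len) + 1L)
    left <- substr(left_raw, nchar(left_raw) - left_len + 1L, nchar(left_raw))
    right <- substr(right_raw, 1L, right_len)
    seqfull <- paste0(left, core, right)

    list(record = new_seq_records("SYNTH_ALPHOID_ARCHETYPE", seqfull,
                                  "synthetic archetype array (sim_archetype_array)"),
         monomer_consensus = base,
         site = HINDIII_SITE,
         box_offset = box_at,
         unit_len = unit_len, k = k, n_core = n_core,
         core_start = left_len + 1L, core_len = core_len,
         copies = copies, ancestor_unit = ancestor,
         dvns = dvns, n_dvn_columns = length(unique(dvns$column)),
         sporadic = spor,
         domains = list(s1 = s1_members, s3 = s3_members, s2 = s2_members),
         pair = c(32L, 33L))
  })
}
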