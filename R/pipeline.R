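## cli_pipeline: end-to-end orchestration of decompose -> align/variants ->
## segment/events (-> compare) with a single JSON + TSV report bundle.
## Configs are flat lists (or YAML files); every parameter is echoed into the
## report for provenance. Result files carry no timestamps, so re-running a
## configuration reproduces them byte-for-byte; timestamps live in run.log.

PIPELINE_DEFAULTS <- list(
  input = NULL,            # path to FASTA/GenBank, or a seq_records object
  input_format = "fasta",
  second_set = NULL,       # optional second repeat set (path or seq_records)
  second_set_format = "fasta",
  monomer_consensus = NULL,
  site = "AAGCTT",
  anchor = "restriction_site",
  k = NULL,                # HOR period override; inferred when NULL
  min_monomer_identity = 0.60,
  max_divergence = 0.05,
  min_share = 2L,
  tau = 0.2,
  beta = 0.05,
  k_min = 3L,
  dup_min_identity = 0.995,
  out_dir = NULL,
  seed = 1L
)

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), names(PIPELINE_DEFAULTS))
  if (length(unknown)) {
    adom_stop(sprintf("unknown configuration key(s): %s",
                      paste(unknown, collapse = ", ")), "config")
  }
  modifyList(PIPELINE_DEFAULTS, config)
}

stage <- function(name, log_con, expr) {
  cat(sprintf("[%s] stage '%s' start\n", format(Sys.time()), name), file = log_con)
  out <- tryCatch(expr, error = function(e) {
    cat(sprintf("[%s] stage '%s' FAILED: %s\n", format(Sys.time()), name,
                conditionMessage(e)), file = log_con)
    adom_stop(sprintf("stage '%s': %s", name, conditionMessage(e)), "stage")
  })
  cat(sprintf("[%s] stage '%s' done\n", format(Sys.time()), name), file = log_con)
  out
}

#' Run the full array-analysis pipeline
#'
#' Orchestrates monomer/HOR decomposition, consensus-anchored alignment and
#' DVN calling, domain segmentation with barrier / duplicate-pair /
#' conversion-tract inference, and (when a second repeat set is configured) a
#' set comparison. Stage outputs are written as TSV/FASTA/JSON under
#' `out_dir` with a manifest; the top-level report collects unit count, HOR
#' period and length, DVN positions, sporadic rate, the domain map, event
#' calls, and the comparison.
#'
#' @param config A flat named list, or the path to a YAML file with the same
#'   keys. Unknown keys are rejected before any computation. See
#'   `alphadom:::PIPELINE_DEFAULTS` for the full key set and defaults.
#' @return The report, invisibly (a named list, also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  if (is.null(cfg$out_dir)) adom_stop("config needs an out_dir", "config")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(cfg$out_dir, "run.log"), "a")
  on.exit(close(log_con))
  fail_marker <- file.path(cfg$out_dir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  outputs <- character(0)
  emit <- function(x, name, format = "tsv") {
    path <- file.path(cfg$out_dir, name)
    write_report(x, path, format = format)
    outputs <<- c(outputs, name)
    path
  }
  res <- tryCatch({
    records <- stage("load", log_con, {
      if (is.character(cfg$input)) load_sequences(cfg$input, cfg$input_format)
      else if (inherits(cfg$input, "seq_records")) cfg$input
      else adom_stop("config 'input' must be a path or seq_records", "config")
    })

    monomers <- stage("decompose", log_con, {
      detect_monomers(records, monomer_consensus = cfg$monomer_consensus,
                      min_identity = cfg$min_monomer_identity)
    })
    emit(monomers$calls, "monomers.tsv")

    period <- stage("hor_period", log_con, {
      if (!is.null(cfg$k)) list(k = as.integer(cfg$k), lag_profile = NULL)
      else infer_hor_period(monomers)
    })

    phasing <- stage("phase", log_con, {
      phase_hors(monomers, period$k, anchor = cfg$anchor, site = cfg$site)
    })
    emit(phasing$units, "units.tsv")

    fragments <- stage("digest", log_con, digest_insilico(records, cfg$site))

    core <- stage("core", log_con, extract_core(phasing, cfg$max_divergence))
    emit(data.frame(id = names(core$unit_seqs),
                    start = core$units$start, end = core$units$end),
         "core_units.tsv")

    aln <- stage("align", log_con, anchor_align(core$unit_seqs))
    save_alignment(aln, file.path(cfg$out_dir, "core_alignment.afa"),
                   "aligned_fasta")
    outputs <- c(outputs, "core_alignment.afa")
    save_sequences(setNames(paste(aln$consensus[aln$consensus != "-"],
                                  collapse = ""), "consensus"),
                   file.path(cfg$out_dir, "consensus.fasta"))
    outputs <- c(outputs, "consensus.fasta")

    part <- stage("variants", log_con, {
      classify_dvns(call_variants(aln),
                    n_copies = nrow(aln$mat) - length(aln$excluded),
                    min_share = cfg$min_share)
    })
    emit(as.data.frame(part), "variants.tsv")
    rate <- sporadic_rate(part, aln)

    hm <- haplotype_matrix(part, aln$copy_ids)
    map <- stage("segment", log_con, {
      detect_barriers(segment_domains(hm, tau = cfg$tau), hm, beta = cfg$beta)
    })
    emit(map, "domain_map.json", format = "json")

    pairs <- stage("events", log_con,
                   detect_duplicate_pairs(aln, part, cfg$dup_min_identity))
    emit(pairs, "duplicate_pairs.tsv")
    tracts <- stage("events", log_con,
                    detect_conversion_tracts(hm, map, k_min = cfg$k_min))
    emit(tracts, "conversion_tracts.tsv")

    comparison <- NULL
    if (!is.null(cfg$second_set)) {
      comparison <- stage("compare", log_con, {
        second <- if (is.character(cfg$second_set)) {
          load_sequences(cfg$second_set, cfg$second_set_format)
        } else cfg$second_set
        compare_sets(core$unit_seqs, as_dna(second), seed = cfg$seed)
      })
    }

    unit_lens <- nchar(core$unit_seqs)
    report <- list(
      config = cfg[!vapply(cfg, is.object, logical(1))],
      unit_count = length(core$unit_seqs),
      k = period$k,
      hor_length = as.integer(names(which.max(table(unit_lens)))),
      digest_modal_fragment = as.integer(names(which.max(table(fragments)))),
      dvn_columns = part$dvn_columns,
      n_dvn_groups = nrow(part$dvns),
      n_sporadic = nrow(part$sporadic),
      sporadic_rate_pct = rate$rate_pct,
      domains = map$domains,
      barriers = map$barriers,
      unassigned = map$unassigned,
      duplicate_pairs = pairs,
      conversion_tracts = tracts,
      comparison = if (!is.null(comparison)) {
        list(shared = comparison$shared, private_a = comparison$private_a,
             private_b = comparison$private_b,
             intermingling = comparison$intermingling[c("raw", "index", "p_value")],
             newick = comparison$newick)
      }
    )
    report$config$input <- if (is.character(cfg$input)) cfg$input else "<in-memory>"
    report$config$second_set <-
      if (is.null(cfg$second_set)) NULL
      else if (is.character(cfg$second_set)) cfg$second_set else "<in-memory>"
    emit(report, "report.json", format = "json")
    writeLines(c("# pipeline output manifest", sort(unique(outputs))),
               file.path(cfg$out_dir, "MANIFEST"))
    report
  }, error = function(e) {
    writeLines(conditionMessage(e), fail_marker)
    stop(e)
  })
  invisible(res)
}
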