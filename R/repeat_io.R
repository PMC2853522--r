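## repeat_io: reading/writing the external formats the pipeline touches and
## normalising everything into the internal data model.
##
## Sequence collections are plain data frames (id, sequence, source) of class
## "seq_records"; alignments are character matrices wrapped in an
## "array_alignment" object (see align_variants.R). Coordinates are 1-based
## closed intervals, the Bioconductor convention.

VALID_BASES <- c("A", "C", "G", "T", "N")

new_seq_records <- function(id, sequence, source) {
  out <- data.frame(
    id = as.character(id),
    sequence = as.character(sequence),
    source = as.character(source),
    stringsAsFactors = FALSE
  )
  class(out) <- c("seq_records", "data.frame")
  out
}

validate_sequences <- function(ids, seqs, where) {
  if (length(seqs) == 0) {
    adom_stop(sprintf("no sequence records found in %s", where), "empty_input")
  }
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    offender <- ids[which(bad)[1]]
    badchar <- sub(".*?([^ACGTN]).*", "\\1",
                   seqs[which(bad)[1]])
    adom_stop(
      sprintf(
        "record '%s' contains character '%s' outside the DNA alphabet {A,C,G,T,N}",
        offender, badchar
      ),
      "validation"
    )
  }
  if (any(!nzchar(seqs))) {
    adom_stop(sprintf("record '%s' has an empty sequence",
                      ids[which(!nzchar(seqs))[1]]), "validation")
  }
  seqs
}

#' Load DNA sequences from FASTA or GenBank flat files
#'
#' Records are returned in file order with sequences uppercased and validated
#' against the DNA alphabet \{A,C,G,T,N\} ('U' and other characters are
#' rejected, naming the offending record). For GenBank input the full record
#' sequence (ORIGIN block) is returned as one record per entry.
#'
#' @param path Path to the file.
#' @param format `"fasta"` or `"genbank"`.
#' @return A `seq_records` data frame with columns `id`, `sequence`, `source`.
#' @export
load_sequences <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    adom_stop(sprintf("cannot read '%s': file does not exist", path), "io")
  }
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) adom_stop(
                      sprintf("failed to parse FASTA '%s': %s", path,
                              conditionMessage(e)), "io"))
    ids <- sub("\\s.*$", "", names(set))
    seqs <- validate_sequences(ids, as.character(set), path)
    return(new_seq_records(ids, seqs, path))
  }
  parse_genbank(path)
}

## Minimal GenBank flat-file reader: LOCUS name + ORIGIN sequence per entry.
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ids <- character(0); seqs <- character(0)
  cur_id <- NULL; in_origin <- FALSE; buf <- character(0)
  for (ln in lines) {
    if (grepl("^LOCUS", ln)) {
      cur_id <- strsplit(trimws(sub("^LOCUS", "", ln)), "\\s+")[[1]][1]
    } else if (grepl("^ACCESSION", ln) && (is.null(cur_id) || cur_id == "")) {
      cur_id <- strsplit(trimws(sub("^ACCESSION", "", ln)), "\\s+")[[1]][1]
    } else if (grepl("^ORIGIN", ln)) {
      in_origin <- TRUE
    } else if (grepl("^//", ln)) {
      ids <- c(ids, cur_id %||% sprintf("record_%d", length(ids) + 1L))
      seqs <- c(seqs, paste(buf, collapse = ""))
      cur_id <- NULL; in_origin <- FALSE; buf <- character(0)
    } else if (in_origin) {
      buf <- c(buf, gsub("[^A-Za-z]", "", ln))
    }
  }
  seqs <- validate_sequences(ids, seqs, path)
  new_seq_records(ids, seqs, path)
}

#' Save sequences as FASTA
#'
#' @param records A `seq_records` data frame, or a named character vector.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @export
save_sequences <- function(records, path, width = 70L) {
  seqs <- as_dna(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Coerce a sequence collection to a named character vector
#' @param x A `seq_records` data frame or (named) character vector.
#' @export
as_dna <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- sprintf("seq_%d", seq_along(x))
    return(x)
  }
  if (is.data.frame(x)) return(setNames(x$sequence, x$id))
  adom_stop("cannot interpret input as a sequence collection", "validation")
}

#' Load a multiple alignment from Clustal or aligned-FASTA
#'
#' Rows are returned in file order; gap characters ('.', '-') are normalised
#' to '-'. All rows must share one aligned length.
#'
#' @param path Path to the alignment file.
#' @param format `"clustal"` or `"aligned_fasta"`.
#' @return An [array_alignment] object.
#' @export
load_alignment <- function(path, format = c("clustal", "aligned_fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    adom_stop(sprintf("cannot read '%s': file does not exist", path), "io")
  }
  if (format == "aligned_fasta") {
    set <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(set))
    rows <- toupper(chartr(".", "-", as.character(set)))
  } else {
    parsed <- parse_clustal(path)
    ids <- parsed$ids
    rows <- parsed$rows
  }
  if (length(rows) == 0) adom_stop(sprintf("empty alignment in %s", path), "empty_input")
  if (length(unique(nchar(rows))) != 1) {
    adom_stop(sprintf("ragged alignment in %s: row lengths %s", path,
                      paste(unique(nchar(rows)), collapse = ", ")), "validation")
  }
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(mat) <- ids
  alignment_from_matrix(mat)
}

parse_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^CLUSTAL", lines[1])) {
    adom_stop(sprintf("'%s' does not look like a clustal file", path), "validation")
  }
  body <- lines[-1]
  ids <- character(0)
  seqs <- list()
  for (ln in body) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s", ln)) next            # conservation line
    m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z.\\-]+)\\s*\\d*$", ln))[[1]]
    if (length(m) != 3) next
    id <- m[2]; seg <- m[3]
    if (!id %in% ids) {
      ids <- c(ids, id)
      seqs[[id]] <- seg
    } else {
      seqs[[id]] <- paste0(seqs[[id]], seg)
    }
  }
  rows <- toupper(chartr(".", "-", unlist(seqs[ids], use.names = FALSE)))
  list(ids = ids, rows = rows)
}

#' Save an alignment as Clustal or aligned-FASTA
#'
#' @param aln An [array_alignment].
#' @param path Output path.
#' @param format `"clustal"` or `"aligned_fasta"`.
#' @export
save_alignment <- function(aln, path, format = c("clustal", "aligned_fasta")) {
  format <- match.arg(format)
  rows <- apply(aln$mat, 1, paste, collapse = "")
  ids <- aln$copy_ids
  if (format == "aligned_fasta") {
    return(save_sequences(setNames(rows, ids), path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("CLUSTAL multiple sequence alignment (alphadom)", con)
  writeLines("", con)
  width <- 60L
  idw <- max(nchar(ids)) + 4L
  for (s in seq(1L, nchar(rows[1]), by = width)) {
    for (i in seq_along(ids)) {
      writeLines(sprintf("%-*s%s", idw, ids[i],
                         substr(rows[i], s, min(s + width - 1L, nchar(rows[i])))), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Write a pipeline product as TSV or JSON
#'
#' Tabular products (data frames, or objects with an `as.data.frame` method
#' such as variant partitions and domain maps) are written as TSV with a
#' header row and deterministic column order; any product can be written as
#' JSON, which is stable under re-serialisation.
#'
#' @param x The product to serialise.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (format == "tsv") {
    df <- as.data.frame(x)
    ok <- tryCatch({
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) adom_stop(sprintf("cannot write '%s'", path), "io")
  } else {
    json <- jsonlite::toJSON(report_payload(x), auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, null = "null")
    ok <- tryCatch({ writeLines(json, path); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) adom_stop(sprintf("cannot write '%s'", path), "io")
  }
  invisible(path)
}

## JSON payload for a product: strip classes so serialisation is plain.
report_payload <- function(x) {
  if (is.data.frame(x)) {
    y <- x; class(y) <- "data.frame"
    return(y)
  }
  if (inherits(x, "domain_map")) return(domain_map_payload(x))
  if (is.list(x)) return(lapply(unclass(x), report_payload))
  x
}

#' Read back a TSV report as a data frame
#' @param path Path written by [write_report()].
#' @export
read_report <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
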