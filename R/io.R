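#' Build a table of protein records
#'
#' Assembles and validates the tibble of protein records used throughout the
#' package: one row per protein with its sequence and (optional) annotation.
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of amino-acid sequences. Only the twenty
#'   canonical one-letter codes plus the ambiguity code `X` are accepted;
#'   lower-case input is upper-cased.
#' @param description Free-text description (defaults to `""`).
#' @param taxon One of `"plant"`, `"animal"`, `"fungus"`, `"other"`,
#'   `"unknown"` (default).
#' @param localisation Annotated localisation: `"secreted"`, `"cytoplasmic"`,
#'   `"mitochondrial"`, `"membrane"` or `"none"` (default).
#' @param score Integer annotation-evidence score in 0--5; 0 (default) means
#'   no annotation. Mirrors curated database evidence scores where 5 is
#'   complete experimental evidence.
#'
#' @return A tibble with columns `id`, `description`, `sequence`, `taxon`,
#'   `localisation`, `score`.
#' @export
#'
#' @examples
#' protein_records("p1", "MAESGSSSEP")
protein_records <- function(id, sequence, description = "",
                            taxon = "unknown", localisation = "none",
                            score = 0L) {
  records <- tibble(
    id = as.character(id),
    description = as.character(description),
    sequence = toupper(as.character(sequence)),
    taxon = as.character(taxon),
    localisation = as.character(localisation),
    score = as.integer(score)
  )
  validate_records(records)
}

validate_records <- function(records) {
  records <- as_tibble(records)
  needed <- c("id", "sequence")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("records table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"description" %in% names(records)) records$description <- ""
  if (!"taxon" %in% names(records)) records$taxon <- "unknown"
  if (!"localisation" %in% names(records)) records$localisation <- "none"
  if (!"score" %in% names(records)) records$score <- 0L
  records$sequence <- toupper(records$sequence)
  if (anyDuplicated(records$id)) {
    abort("duplicate record ids")
  }
  bad_seq <- !grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", records$sequence)
  if (any(bad_seq)) {
    abort(paste0("invalid residue characters in sequence(s): ",
                 paste(records$id[bad_seq], collapse = ", ")))
  }
  if (any(records$score < 0 | records$score > 5)) {
    abort("annotation score outside 0-5")
  }
  bad_tax <- !records$taxon %in% TAXA
  if (any(bad_tax)) abort("unknown taxon value")
  bad_loc <- !records$localisation %in% LOCALISATIONS
  if (any(bad_loc)) abort("unknown localisation value")
  records[c("id", "description", "sequence", "taxon", "localisation", "score")]
}

#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) FASTA file into a record tibble. The
#' parser is strict: any residue outside the twenty canonical amino-acid
#' letters plus `X` raises an error naming the offending line, so typos and
#' nucleotide files are caught at the door rather than downstream.
#'
#' @param path Path to a FASTA file.
#' @return A record tibble as from [protein_records()]; annotation columns
#'   default to `unknown`/`none`/`0` until [attach_metadata()] supplies them.
#' @seealso [write_fasta()], [attach_metadata()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0) abort("empty FASTA input")
  ids <- character()
  descs <- character()
  seqs <- character()
  current <- NULL
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "") next
    if (startsWith(line, ">")) {
      header <- sub("^>\\s*", "", line)
      if (header == "") {
        abort(paste0("malformed FASTA header at line ", i))
      }
      id <- sub("\\s.*$", "", header)
      desc <- sub("^\\S+\\s*", "", header)
      ids <- c(ids, id)
      descs <- c(descs, desc)
      seqs <- c(seqs, "")
      current <- length(seqs)
    } else {
      if (is.null(current)) {
        abort(paste0("sequence data before first header at line ", i))
      }
      chunk <- toupper(gsub("\\s", "", line))
      if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]*$", chunk)) {
        abort(paste0("illegal residue character at line ", i))
      }
      seqs[[current]] <- paste0(seqs[[current]], chunk)
    }
  }
  if (any(seqs == "")) {
    abort(paste0("record(s) with empty sequence: ",
                 paste(ids[seqs == ""], collapse = ", ")))
  }
  protein_records(id = ids, sequence = seqs, description = descs)
}

#' Write protein records to a FASTA file
#'
#' @param records A record tibble.
#' @param path Output path.
#' @param width Line-wrap width for sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  records <- validate_records(records)
  out <- unlist(purrr::map2(records$id, seq_len(nrow(records)), function(id, i) {
    desc <- records$description[[i]]
    header <- if (nzchar(desc)) paste0(">", id, " ", desc) else paste0(">", id)
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", records$sequence[[i]])
    c(header, strsplit(body, "\n")[[1]])
  }))
  writeLines(out, path)
  invisible(path)
}

#' Attach sidecar metadata to protein records
#'
#' Joins a tab-separated annotation table (columns `id`, `taxon`,
#' `localisation`, `score`) onto a record tibble, mirroring the tabular
#' supplements that usually accompany published motif surveys. Records
#' without a matching row are left unchanged; table rows without a matching
#' record produce a warning, not a failure.
#'
#' @param records A record tibble.
#' @param table Path to a TSV file, or a data frame with the same columns.
#' @return The record tibble with `taxon`, `localisation` and `score`
#'   filled in for matched ids.
#' @export
attach_metadata <- function(records, table) {
  records <- validate_records(records)
  meta <- if (is.character(table)) {
    readr::read_tsv(table, show_col_types = FALSE, progress = FALSE)
  } else {
    as_tibble(table)
  }
  needed <- c("id", "taxon", "localisation", "score")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(meta$id)) abort("duplicate id in metadata table")
  meta$score <- as.integer(meta$score)
  if (any(is.na(meta$score)) || any(meta$score < 0 | meta$score > 5)) {
    abort("metadata score outside 0-5")
  }
  unmatched <- setdiff(meta$id, records$id)
  if (length(unmatched) > 0) {
    warn(paste0("metadata rows with no matching record: ",
                paste(unmatched, collapse = ", ")))
  }
  idx <- match(records$id, meta$id)
  hit <- !is.na(idx)
  records$taxon[hit] <- meta$taxon[idx[hit]]
  records$localisation[hit] <- meta$localisation[idx[hit]]
  records$score[hit] <- meta$score[idx[hit]]
  validate_records(records)
}

#' Convert internal to reported coordinates
#'
#' Internally all regions are 0-based half-open `[start0, end0)`; everything
#' written for users is 1-based inclusive, the convention of protein residue
#' numbering (the canonical motif at internal `[16, 27)` is reported as
#' residues 17--27).
#'
#' @param start0,end0 Integer vectors, 0-based half-open.
#' @return A tibble with columns `start`, `end` (1-based inclusive).
#' @export
region_external <- function(start0, end0) {
  stopifnot(all(start0 >= 0), all(end0 > start0))
  tibble(start = as.integer(start0) + 1L, end = as.integer(end0))
}

#' Convert reported to internal coordinates
#'
#' Inverse of [region_external()].
#'
#' @param start,end Integer vectors, 1-based inclusive.
#' @return A tibble with columns `start0`, `end0` (0-based half-open).
#' @export
region_internal <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  tibble(start0 = as.integer(start) - 1L, end0 = as.integer(end))
}

#' Write a result table to TSV or JSON
#'
#' Columns are emitted in their existing (deterministic) order; both formats
#' carry identical values so that a JSON and a TSV export of the same result
#' round-trip to the same table.
#'
#' @param x A data frame (scan results, localisation calls, count tables...).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- arg_match(format)
  x <- as_tibble(x)
  x <- dplyr::select(x, !dplyr::where(is.list))
  if (format == "tsv") {
    readr::write_tsv(x, path, progress = FALSE)
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a result table written by [write_report()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @return A tibble.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- arg_match(format)
  if (format == "tsv") {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    as_tibble(jsonlite::fromJSON(path))
  }
}
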