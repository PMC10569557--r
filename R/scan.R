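#' Quarter of the primary structure holding a position
#'
#' Classifies a motif start position into quarters of the protein: `P1` is
#' the N-terminal 25% of the primary structure, `P4` the C-terminal 25%.
#' The *start* of the motif window anchors the assignment.
#'
#' @param start0 Integer vector of 0-based start positions.
#' @param seq_len Sequence length (positive integer).
#' @return Character vector of `"P1"`..`"P4"`.
#' @export
#'
#' @examples
#' quarter_of(16, 150)  # "P1"
#' quarter_of(75, 100)  # "P4"
quarter_of <- function(start0, seq_len) {
  if (any(seq_len <= 0)) abort("seq_len must be positive")
  if (any(start0 < 0) || any(start0 >= seq_len)) {
    abort("start0 outside [0, seq_len)")
  }
  q <- pmin(floor(4 * start0 / seq_len), 3)
  QUARTERS[q + 1L]
}

# Profile as a 21 x 11 logical lookup: row = residue code, column = position.
profile_lookup <- function(profile) {
  m <- matrix(FALSE, nrow = length(AA_ALPHABET), ncol = profile$length,
              dimnames = list(AA_ALPHABET, NULL))
  for (p in seq_len(profile$length)) {
    m[profile$allowed[[p]], p] <- TRUE
  }
  m
}

# Vectorised core scores of all full-length forward/inverted windows.
# codes: integer codes of the sequence in AA_ALPHABET; returns a numeric
# vector over 0-based starts 0..L-11 (length 0 when L < 11).
window_scores <- function(codes, lookup, core_span, inverted = FALSE) {
  L <- length(codes)
  n <- L - 11L + 1L
  if (n <= 0) return(integer(0))
  scores <- integer(n)
  s0 <- 0:(n - 1L)
  for (j in core_span) {
    idx <- if (inverted) s0 + 12L - j else s0 + j
    scores <- scores + lookup[cbind(codes[idx], j)]
  }
  scores
}

# Scan one sequence. Core-only (8-mer) windows are evaluated only where the
# enclosing 11-mer window falls off the sequence end: every interior 8-mer is
# the core of an 11-mer window with an identical score (positions 1-3 are
# wildcards), so reporting it would duplicate the full-length hit.
scan_one <- function(sequence, profile, lookup, min_score,
                     allow_inverted, allow_core_only) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  empty <- tibble(start0 = integer(), width = integer(),
                  orientation = character(), score = integer(),
                  is_core_only = logical())
  if (L < 8) return(empty)
  codes <- match(chars, AA_ALPHABET)

  out <- list()
  fwd11 <- window_scores(codes, lookup, profile$core_span, inverted = FALSE)
  if (length(fwd11) > 0) {
    keep <- which(fwd11 >= min_score)
    if (length(keep) > 0) {
      out[[length(out) + 1L]] <- tibble(
        start0 = keep - 1L, width = 11L, orientation = "forward",
        score = as.integer(fwd11[keep]), is_core_only = FALSE
      )
    }
  }
  if (allow_inverted) {
    inv11 <- window_scores(codes, lookup, profile$core_span, inverted = TRUE)
    keep <- which(inv11 >= min_score)
    if (length(keep) > 0) {
      out[[length(out) + 1L]] <- tibble(
        start0 = keep - 1L, width = 11L, orientation = "inverted",
        score = as.integer(inv11[keep]), is_core_only = FALSE
      )
    }
  }
  if (allow_core_only) {
    starts8 <- 0:(L - 8L)
    fwd_edge <- starts8[starts8 < 3L]
    for (s0 in fwd_edge) {
      w <- substr(sequence, s0 + 1L, s0 + 8L)
      sc <- score_window(w, profile)
      if (sc >= min_score) {
        out[[length(out) + 1L]] <- tibble(
          start0 = s0, width = 8L, orientation = "forward",
          score = as.integer(sc), is_core_only = TRUE
        )
      }
    }
    if (allow_inverted) {
      inv_edge <- starts8[starts8 + 11L > L]
      for (s0 in inv_edge) {
        w <- substr(sequence, s0 + 1L, s0 + 8L)
        sc <- score_window(paste(rev(strsplit(w, "")[[1]]), collapse = ""),
                           profile)
        if (sc >= min_score) {
          out[[length(out) + 1L]] <- tibble(
            start0 = s0, width = 8L, orientation = "inverted",
            score = as.integer(sc), is_core_only = TRUE
          )
        }
      }
    }
  }
  if (length(out) == 0) return(empty)
  arrange(bind_rows(out), .data$start0, .data$orientation, .data$width)
}

#' Scan proteins for N-beta-like motifs
#'
#' Slides the position-specific profile across every sequence and reports
#' all windows whose core score reaches `min_score`. Both orientations are
#' searched by default (the motif works when its sequence is inverted), and
#' bare 8-residue cores are accepted at sequence ends where the full 11-mer
#' window cannot fit. All overlapping hits are reported; downstream rules
#' choose among them.
#'
#' @param records A record tibble (see [protein_records()] / [read_fasta()]).
#' @param profile An [nbeta_profile()].
#' @param min_score Minimum core score to report: 8 (strict, the default)
#'   requires all eight core positions to match; 6 is the conventional
#'   relaxed setting for exploratory scans.
#' @param allow_inverted Also score each window reversed (default `TRUE`).
#' @param allow_core_only Accept 8-mer core hits at sequence ends
#'   (default `TRUE`).
#'
#' @return A tibble with one row per hit: `id`, `start`, `end` (1-based
#'   inclusive residue coordinates), `width`, `orientation`, `window` (the
#'   residues as they appear in the protein), `score`, `is_core_only`,
#'   `quarter` (`P1`--`P4`, anchored at the window start),
#'   `n_terminal_quarter` and `at_c_terminus` (window ends at the final
#'   residue), plus `seq_len`.
#' @export
#'
#' @examples
#' recs <- protein_records("demo", paste0("MKL", canonical_nbeta(), "GGGG"))
#' scan_proteins(recs)
scan_proteins <- function(records, profile = nbeta_profile(),
                          min_score = 8L, allow_inverted = TRUE,
                          allow_core_only = TRUE) {
  records <- validate_records(records)
  if (min_score < 0 || min_score > 8) abort("min_score must be in 0-8")
  lookup <- profile_lookup(profile)
  hits <- purrr::map2(records$id, records$sequence, function(id, seq) {
    h <- scan_one(seq, profile, lookup, min_score,
                  allow_inverted, allow_core_only)
    if (nrow(h) == 0) return(NULL)
    L <- nchar(seq)
    h %>%
      mutate(
        id = id,
        seq_len = L,
        end0 = .data$start0 + .data$width,
        window = substr(rep(seq, n()), .data$start0 + 1L, .data$end0),
        quarter = quarter_of(.data$start0, L),
        n_terminal_quarter = .data$quarter == "P1",
        at_c_terminus = .data$end0 == L
      )
  })
  hits <- bind_rows(hits)
  if (nrow(hits) == 0) {
    return(tibble(
      id = character(), start = integer(), end = integer(),
      width = integer(), orientation = character(), window = character(),
      score = integer(), is_core_only = logical(), quarter = character(),
      n_terminal_quarter = logical(), at_c_terminus = logical(),
      seq_len = integer()
    ))
  }
  hits %>%
    mutate(start = .data$start0 + 1L, end = .data$end0) %>%
    select("id", "start", "end", "width", "orientation", "window",
           "score", "is_core_only", "quarter", "n_terminal_quarter",
           "at_c_terminus", "seq_len")
}
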