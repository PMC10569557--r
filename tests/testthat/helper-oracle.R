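# Shared helpers: random sequences and a brute-force reference scanner that
# enumerates every window with score_window(). The reference path is kept
# deliberately loop-based and independent of the vectorised scanner.

AA20_TEST <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) {
  paste(sample(AA20_TEST, len, replace = TRUE), collapse = "")
}

reverse_string <- function(s) {
  paste(rev(strsplit(s, "")[[1]]), collapse = "")
}

# Enumerate all candidate windows: every 11-mer in both orientations, plus
# 8-mer cores where the enclosing 11-mer does not fit (forward: the first
# three starts; inverted: starts within 11 of the C-terminus).
brute_force_scan <- function(sequence, profile = nbeta_profile(),
                             min_score = 8, allow_inverted = TRUE,
                             allow_core_only = TRUE) {
  L <- nchar(sequence)
  rows <- list()
  add <- function(start0, width, orientation, score, core_only) {
    if (score >= min_score) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        start0 = start0, width = width, orientation = orientation,
        score = as.integer(score), is_core_only = core_only
      )
    }
  }
  if (L >= 11) {
    for (s0 in 0:(L - 11)) {
      w <- substr(sequence, s0 + 1, s0 + 11)
      add(s0, 11L, "forward", score_window(w, profile), FALSE)
      if (allow_inverted) {
        add(s0, 11L, "inverted", score_window(reverse_string(w), profile),
            FALSE)
      }
    }
  }
  if (allow_core_only && L >= 8) {
    for (s0 in 0:(L - 8)) {
      w <- substr(sequence, s0 + 1, s0 + 8)
      if (s0 < 3) {
        add(s0, 8L, "forward", score_window(w, profile), TRUE)
      }
      if (allow_inverted && s0 + 11 > L) {
        add(s0, 8L, "inverted", score_window(reverse_string(w), profile),
            TRUE)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(start0 = integer(), width = integer(),
                          orientation = character(), score = integer(),
                          is_core_only = logical()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), start0, orientation, width)
}

# Normalised view of scan_proteins() output for comparison with the oracle.
scan_normalised <- function(sequence, ...) {
  recs <- protein_records("q", sequence)
  hits <- scan_proteins(recs, ...)
  dplyr::arrange(
    tibble::tibble(
      start0 = hits$start - 1L, width = hits$width,
      orientation = hits$orientation, score = hits$score,
      is_core_only = hits$is_core_only
    ),
    start0, orientation, width
  )
}

# Plant a motif into a background by overwriting at a 0-based start.
plant_motif <- function(background, motif, start0) {
  substr(background, start0 + 1, start0 + nchar(motif)) <- motif
  background
}
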