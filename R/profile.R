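#' The canonical N-beta motif
#'
#' Returns the eleven-residue reference motif. Positions 4--11 are the
#' experimentally attested core `ESGSSSEP`; positions 1--3 are the least
#' conserved part of the motif and are represented by the placeholder `A`
#' (they are wildcards in the profile, so the placeholder never influences
#' scoring or classification).
#'
#' @return An 11-character string, `"AAAESGSSSEP"`.
#' @export
#'
#' @examples
#' canonical_nbeta()
canonical_nbeta <- function() {
  "AAAESGSSSEP"
}

#' Named N-beta motif variants
#'
#' Builds the motif variants used in the functional dissection of the signal:
#' single-residue substitutions (`S5G`, `S8A`, `S8D`, `S8E`, `S9A`), the
#' double substitution associated with mitochondrial targeting
#' (`A5E8_mito`: Ala-5 together with Glu-8), the N-terminal deletions
#' (`minus3` keeps the functional 8-residue core, `minus6` truncates into
#' it), and the full reversal (`inverted`).
#'
#' @param name One of `"canonical"`, `"S5G"`, `"S8A"`, `"S8D"`, `"S8E"`,
#'   `"S9A"`, `"A5E8_mito"`, `"minus3"`, `"minus6"`, `"inverted"`.
#' @return The variant sequence as a string.
#' @export
#'
#' @examples
#' nbeta_variant("S9A")
#' nbeta_variant("minus3")
nbeta_variant <- function(name = c("canonical", "S5G", "S8A", "S8D", "S8E",
                                   "S9A", "A5E8_mito", "minus3", "minus6",
                                   "inverted")) {
  name <- arg_match(name)
  canon <- canonical_nbeta()
  substitute_at <- function(seq, pos, res) {
    substr(seq, pos, pos) <- res
    seq
  }
  switch(name,
    canonical = canon,
    S5G = substitute_at(canon, 5, "G"),
    S8A = substitute_at(canon, 8, "A"),
    S8D = substitute_at(canon, 8, "D"),
    S8E = substitute_at(canon, 8, "E"),
    S9A = substitute_at(canon, 9, "A"),
    A5E8_mito = substitute_at(substitute_at(canon, 5, "A"), 8, "E"),
    minus3 = substr(canon, 4, 11),
    minus6 = substr(canon, 7, 11),
    inverted = paste(rev(strsplit(canon, "")[[1]]), collapse = "")
  )
}

#' The position-specific N-beta profile
#'
#' The motif model used by the scanner: for each of the eleven positions, the
#' set of residues compatible with an N-beta-like motif. Positions 1--3 are
#' wildcards (any residue); positions 4--11 form the required core. The
#' allowed sets cover the residues observed across both secretory and
#' cytoplasmic/mitochondrial motif carriers -- the scanner finds *motif-like*
#' windows, and the rule engine ([classify_match()]) then separates fates.
#'
#' @return An object of class `nbeta_profile`: a list with elements
#'   `length` (11), `allowed` (list of residue sets, one per position),
#'   `core_span` (integer positions 4--11), `canonical` and
#'   `dispensable_prefix` (positions 1--3).
#' @export
#'
#' @examples
#' prof <- nbeta_profile()
#' prof$allowed[[8]]
nbeta_profile <- function() {
  allowed <- c(
    rep(list(AA20), 3),                 # positions 1-3: wildcard
    list("E"),                          # 4
    list(c("S", "G", "A")),             # 5
    list("G"),                          # 6
    list(c("S", "A")),                  # 7
    list(c("S", "E", "D", "A")),        # 8
    list(c("S", "A")),                  # 9
    list(c("E", "D")),                  # 10
    list(c("P", "D"))                   # 11
  )
  profile <- list(
    length = 11L,
    allowed = allowed,
    core_span = 4:11,
    canonical = canonical_nbeta(),
    dispensable_prefix = 1:3
  )
  class(profile) <- "nbeta_profile"
  canon <- strsplit(profile$canonical, "")[[1]]
  stopifnot(all(purrr::map2_lgl(canon, allowed, ~ .x %in% .y)))
  profile
}

#' @export
print.nbeta_profile <- function(x, ...) {
  cat("N-beta motif profile (length ", x$length, ", core ",
      min(x$core_span), "-", max(x$core_span), ")\n", sep = "")
  for (p in seq_len(x$length)) {
    set <- x$allowed[[p]]
    shown <- if (length(set) == 20) "any" else paste(set, collapse = "/")
    cat(sprintf("  %2d: %s\n", p, shown))
  }
  invisible(x)
}

#' Score a single window against the profile
#'
#' Counts how many of the eight core positions (4--11) carry a residue in the
#' profile's allowed set. An 11-mer window is scored at its positions 4--11;
#' an 8-mer window is interpreted as a bare core (positions 4--11 directly).
#' The wildcard prefix never contributes. `X` matches no position.
#'
#' @param window An 8- or 11-character residue string.
#' @param profile An [nbeta_profile()].
#' @return Integer score in 0--8.
#' @export
#'
#' @examples
#' score_window("ESGSSSEP", nbeta_profile())   # 8
#' score_window("KKKKKKKK", nbeta_profile())   # 0
score_window <- function(window, profile = nbeta_profile()) {
  nc <- nchar(window)
  if (!nc %in% c(8L, 11L)) {
    abort("window must be 8 (core) or 11 residues long")
  }
  chars <- strsplit(toupper(window), "")[[1]]
  offset <- if (nc == 11L) 0L else -3L
  hits <- purrr::map_lgl(profile$core_span, function(p) {
    chars[[p + offset]] %in% profile$allowed[[p]]
  })
  sum(hits)
}
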