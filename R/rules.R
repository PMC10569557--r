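#' Configuration of the localisation rules
#'
#' Bundles the residue sets and switches used by [classify_match()]. The
#' defaults encode the experimentally supported plant rules; `taxon_mode =
#' "animal"` switches position 8 to the Glu-8 requirement, which is a
#' hypothesis rather than an assay-proven rule and is flagged as such in the
#' rule trace.
#'
#' @param taxon_mode `"plant"` (default) or `"animal"`.
#' @param neutral_pos9 Residues accepted at motif position 9. Serine is
#'   proven functional and alanine proven non-functional; the default extends
#'   serine to the polar-neutral set `{S,T,N,Q,G}`.
#' @param plant_pos8_secretory Residues at position 8 compatible with
#'   secretion in plant mode (serine proven, alanine proven).
#' @param animal_pos8_secretory Residues at position 8 compatible with
#'   secretion/traffic in animal mode (glutamate; hypothesis).
#' @param mito_pos5,mito_pos8 Residue sets whose joint presence (Ala-5 with
#'   Glu-8) marks a candidate mitochondrial transit peptide in plant mode.
#' @param require_negative_charge Require a net negative charge over the
#'   matched window (default `TRUE`).
#' @param kdel_variants C-terminal tetrapeptides causing ER retention.
#' @return An object of class `nbeta_rule_config`.
#' @export
rule_config <- function(taxon_mode = c("plant", "animal"),
                        neutral_pos9 = c("S", "T", "N", "Q", "G"),
                        plant_pos8_secretory = c("S", "A"),
                        animal_pos8_secretory = "E",
                        mito_pos5 = "A",
                        mito_pos8 = "E",
                        require_negative_charge = TRUE,
                        kdel_variants = c("KDEL", "HDEL")) {
  taxon_mode <- arg_match(taxon_mode)
  stopifnot(
    length(neutral_pos9) > 0, length(plant_pos8_secretory) > 0,
    length(animal_pos8_secretory) > 0, length(kdel_variants) > 0,
    "KDEL" %in% kdel_variants
  )
  structure(
    list(
      taxon_mode = taxon_mode,
      neutral_pos9 = neutral_pos9,
      plant_pos8_secretory = plant_pos8_secretory,
      animal_pos8_secretory = animal_pos8_secretory,
      mito_pos5 = mito_pos5,
      mito_pos8 = mito_pos8,
      require_negative_charge = require_negative_charge,
      kdel_variants = kdel_variants
    ),
    class = "nbeta_rule_config"
  )
}

#' Net charge of a residue string at physiological pH
#'
#' Counts basic minus acidic residues: `(#K + #R) - (#D + #E)`. Histidine is
#' treated as neutral at physiological pH. The motif's overall negative
#' charge (mainly from Glu-4 and Glu-10) is required for it to act as a
#' secretion signal.
#'
#' @param seq Character vector of residue strings.
#' @return Integer vector; the empty string has charge 0.
#' @export
#'
#' @examples
#' net_charge(canonical_nbeta())  # -2
net_charge <- function(seq) {
  count <- function(s, letters) {
    chars <- strsplit(toupper(s), "")[[1]]
    sum(chars %in% letters)
  }
  vapply(seq, function(s) {
    as.integer(count(s, c("K", "R")) - count(s, c("D", "E")))
  }, integer(1), USE.NAMES = FALSE)
}

#' Mean Kyte-Doolittle hydropathy
#'
#' Arithmetic mean of the Kyte-Doolittle hydropathy index over the residues
#' of `seq`; `X` residues are excluded. Negative values indicate a
#' hydrophilic stretch -- the motif's hallmark, in contrast with the
#' hydrophobic core of a classical signal peptide.
#'
#' @param seq Character vector of residue strings.
#' @return Numeric vector of mean hydropathy values.
#' @export
#'
#' @examples
#' mean_hydropathy("IIIII")  # 4.5
mean_hydropathy <- function(seq) {
  vapply(seq, function(s) {
    chars <- strsplit(toupper(s), "")[[1]]
    chars <- chars[chars != "X"]
    if (length(chars) == 0) abort("empty (or all-X) sequence")
    vals <- KYTE_DOOLITTLE[chars]
    if (anyNA(vals)) abort("invalid residue in sequence")
    mean(vals)
  }, numeric(1), USE.NAMES = FALSE)
}

ends_with_retention_signal <- function(sequence, kdel_variants) {
  L <- nchar(sequence)
  L >= 4 && substr(sequence, L - 3, L) %in% kdel_variants
}

#' Classify a single motif match into a subcellular fate
#'
#' Applies the position-, placement-, charge- and retention-rules to one
#' motif hit, in a fixed order, and records every rule consulted in an
#' ordered trace:
#'
#' * **R1 kdel_retention** -- a C-terminal KDEL/HDEL tetrapeptide retains the
#'   protein in the ER regardless of the motif (terminal rule).
#' * **R2 placement** -- the motif must start in the N-terminal quarter or
#'   end at the exact C-terminus; an interior motif is presumed folded into
#'   stable structure and is not recognised.
#' * **R3 core_length** -- all eight core positions (4--11) must be present.
#' * **R4 pos9_neutral** -- position 9 must be polar-neutral.
#' * **R5 pos8_taxon** -- position 8: serine/alanine in plant mode; glutamate
#'   in animal mode (hypothesis, flagged in the trace).
#' * **R6 mito_branch** (plant mode) -- Ala-5 together with Glu-8 marks a
#'   candidate mitochondrial transit peptide.
#' * **R7 net_charge** -- the matched window must be net negative.
#'
#' A match surviving every rule is called `secreted`. Inverted matches are
#' evaluated on the reversed window (net charge is orientation-invariant).
#'
#' @param sequence The full protein sequence the match came from.
#' @param match A one-row data frame as returned by [scan_proteins()].
#' @param config An [rule_config()].
#' @return A list with elements `compartment` and `trace` (a tibble with
#'   columns `rule`, `name`, `fired`, `detail`).
#' @export
classify_match <- function(sequence, match, config = rule_config()) {
  match <- as_tibble(match)
  if (nrow(match) != 1) abort("classify_match expects exactly one match row")
  window_seq <- substr(sequence, match$start, match$end)
  if (!identical(window_seq, match$window)) {
    abort("match does not correspond to the supplied sequence")
  }

  oriented <- if (match$orientation == "inverted") {
    paste(rev(strsplit(match$window, "")[[1]]), collapse = "")
  } else {
    match$window
  }
  core <- if (nchar(oriented) >= 11) substr(oriented, 4, 11) else oriented
  pos <- function(p) substr(core, p - 3, p - 3)

  trace <- list()
  note <- function(rule, name, fired, detail) {
    trace[[length(trace) + 1L]] <<- tibble(
      rule = rule, name = name, fired = fired, detail = detail
    )
  }
  finish <- function(compartment) {
    list(compartment = compartment, trace = bind_rows(trace))
  }

  # R1: ER retention overrides everything.
  kdel <- ends_with_retention_signal(sequence, config$kdel_variants)
  note("R1", "kdel_retention", kdel,
       if (kdel) "C-terminal retention tetrapeptide present" else
         "no C-terminal KDEL/HDEL")
  if (kdel) return(finish("er_retained"))

  # R2: terminal placement (N-terminal quarter or exact C-terminus).
  interior <- !(match$n_terminal_quarter || match$at_c_terminus)
  note("R2", "placement", interior,
       paste0("quarter ", match$quarter,
              if (match$at_c_terminus) ", at C-terminus" else ""))
  if (interior) return(finish("cytoplasmic"))

  # R3: complete 8-residue core.
  truncated <- nchar(core) < 8
  note("R3", "core_length", truncated,
       paste0("core length ", nchar(core)))
  if (truncated) return(finish("cytoplasmic"))

  # R4: position 9 polar-neutral.
  p9_bad <- !pos(9) %in% config$neutral_pos9
  note("R4", "pos9_neutral", p9_bad, paste0("position 9 = ", pos(9)))
  if (p9_bad) return(finish("cytoplasmic"))

  # R5/R6: position 8 by taxon, with the plant mitochondrial branch.
  p8 <- pos(8)
  if (config$taxon_mode == "plant") {
    p8_bad <- !p8 %in% config$plant_pos8_secretory
    note("R5", "pos8_taxon", p8_bad,
         paste0("plant mode, position 8 = ", p8))
    if (p8_bad) {
      mito <- pos(5) %in% config$mito_pos5 && p8 %in% config$mito_pos8
      note("R6", "mito_branch", mito,
           paste0("position 5 = ", pos(5), ", position 8 = ", p8))
      return(finish(if (mito) "mitochondrial_candidate" else "cytoplasmic"))
    }
  } else {
    p8_bad <- !p8 %in% config$animal_pos8_secretory
    note("R5", "pos8_taxon", p8_bad,
         paste0("animal mode (hypothesis: Glu-8 secretory), position 8 = ",
                p8))
    if (p8_bad) return(finish("cytoplasmic"))
  }

  # R7: the window must carry a net negative charge.
  chg <- net_charge(match$window)
  chg_bad <- config$require_negative_charge && chg >= 0
  note("R7", "net_charge", chg_bad, paste0("net charge ", chg))
  if (chg_bad) return(finish("cytoplasmic"))

  finish("secreted")
}

choose_best_call <- function(calls) {
  ord <- order(
    -calls$score,
    COMPARTMENT_PREFERENCE[calls$compartment],
    calls$start
  )
  calls[ord[1], , drop = FALSE]
}

#' Predict the subcellular fate of each protein
#'
#' Scans every record for motif hits, classifies each hit with
#' [classify_match()], and reports the call of the best match per protein
#' (highest score; ties broken by compartment preference
#' secreted > mitochondrial candidate > ER-retained > cytoplasmic, then by
#' smallest start). Proteins without any hit are called `cytoplasmic`.
#'
#' @inheritParams scan_proteins
#' @param config An [rule_config()].
#' @param keep_trace Keep the full per-protein rule trace as a list column
#'   (default `TRUE`).
#' @return A tibble with one row per protein: `id`, `compartment`, `start`,
#'   `end`, `width`, `orientation`, `score`, `quarter`, `at_c_terminus`,
#'   `fired_rules` (comma-separated ids of rules that fired) and, when
#'   `keep_trace`, a `trace` list column.
#' @export
#'
#' @examples
#' recs <- protein_records("demo", paste0("M", canonical_nbeta(),
#'                                        strrep("G", 40)))
#' predict_localisation(recs)
predict_localisation <- function(records, profile = nbeta_profile(),
                                 config = rule_config(), min_score = 8L,
                                 allow_inverted = TRUE,
                                 allow_core_only = TRUE,
                                 keep_trace = TRUE) {
  records <- validate_records(records)
  hits <- scan_proteins(records, profile, min_score,
                        allow_inverted, allow_core_only)
  calls <- purrr::map(seq_len(nrow(records)), function(i) {
    id <- records$id[[i]]
    seq <- records$sequence[[i]]
    h <- hits[hits$id == id, , drop = FALSE]
    if (nrow(h) == 0) {
      return(tibble(
        id = id, compartment = "cytoplasmic",
        start = NA_integer_, end = NA_integer_, width = NA_integer_,
        orientation = NA_character_, score = NA_integer_,
        quarter = NA_character_, at_c_terminus = NA,
        fired_rules = "no_motif",
        trace = list(tibble(rule = "R0", name = "no_motif", fired = TRUE,
                            detail = "no N-beta-like motif found"))
      ))
    }
    classified <- purrr::map(seq_len(nrow(h)), function(k) {
      res <- classify_match(seq, h[k, ], config)
      tibble(
        id = id, compartment = res$compartment,
        start = h$start[[k]], end = h$end[[k]], width = h$width[[k]],
        orientation = h$orientation[[k]], score = h$score[[k]],
        quarter = h$quarter[[k]], at_c_terminus = h$at_c_terminus[[k]],
        fired_rules = paste(res$trace$rule[res$trace$fired], collapse = ","),
        trace = list(res$trace)
      )
    })
    choose_best_call(bind_rows(classified))
  })
  calls <- bind_rows(calls)
  if (!keep_trace) calls$trace <- NULL
  calls
}

#' Evaluate predictions against constructs with known outcomes
#'
#' Runs [predict_localisation()] over a construct panel (by default the
#' built-in GFP-fusion panel, [paper_constructs()]) and compares the
#' predicted compartment with the experimentally observed one.
#'
#' @param constructs A tibble with columns `name`, `sequence`, `expected`
#'   (and optionally `provenance`), as from [paper_constructs()].
#' @param config An [rule_config()].
#' @inheritParams predict_localisation
#' @return An object of class `nbeta_concordance`: the per-construct tibble
#'   (`name`, `expected`, `predicted`, `concordant`, ...) with the overall
#'   concordance fraction as an attribute. Use [tidy()] / [glance()] for the
#'   table and the summary.
#' @export
#'
#' @examples
#' glance(evaluate_constructs())
evaluate_constructs <- function(constructs = paper_constructs(),
                                config = rule_config(),
                                profile = nbeta_profile(),
                                min_score = 8L) {
  constructs <- as_tibble(constructs)
  if (nrow(constructs) == 0) {
    out <- tibble(name = character(), expected = character(),
                  predicted = character(), concordant = logical())
    attr(out, "concordance") <- NA_real_
    class(out) <- c("nbeta_concordance", class(out))
    return(out)
  }
  stopifnot(all(c("name", "sequence", "expected") %in% names(constructs)))
  recs <- protein_records(id = constructs$name,
                          sequence = constructs$sequence)
  calls <- predict_localisation(recs, profile = profile, config = config,
                                min_score = min_score, keep_trace = FALSE)
  out <- constructs %>%
    select(-"sequence") %>%
    left_join(select(calls, "id", predicted = "compartment",
                     "start", "end", "score", "fired_rules"),
              by = c(name = "id")) %>%
    mutate(concordant = .data$expected == .data$predicted)
  attr(out, "concordance") <- mean(out$concordant)
  class(out) <- c("nbeta_concordance", class(out))
  out
}

#' @export
print.nbeta_concordance <- function(x, ...) {
  cat("Construct concordance: ", sum(x$concordant), "/", nrow(x),
      " (", format(attr(x, "concordance"), digits = 4), ")\n\n", sep = "")
  print(as_tibble(x), n = nrow(x))
  invisible(x)
}

#' @rdname evaluate_constructs
#' @param x An `nbeta_concordance` object.
#' @param ... Unused.
#' @export
tidy.nbeta_concordance <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "nbeta_concordance")
  out
}

#' @rdname evaluate_constructs
#' @export
glance.nbeta_concordance <- function(x, ...) {
  tibble(
    n = nrow(x),
    n_concordant = sum(x$concordant),
    concordance = attr(x, "concordance")
  )
}
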