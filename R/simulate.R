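#' Seeded motif-free background segment
#'
#' Draws a random amino-acid segment and verifies that a strict scan (both
#' orientations, edge cores included) finds no motif-like window in it; if
#' the draw happens to contain one, the next seed is tried. Used as the
#' stand-in for folded protein bodies (the thioredoxin core, GFP): the rules
#' depend only on motif placement, so the biological identity of these
#' segments is irrelevant and a verified-neutral random segment is the
#' cleanest carrier.
#'
#' @param length Segment length in residues.
#' @param seed Integer seed (deterministic output).
#' @param max_tries Seeds to try before giving up.
#' @return A residue string of the requested length.
#' @export
motif_free_segment <- function(length, seed = 101L, max_tries = 25L) {
  profile <- nbeta_profile()
  lookup <- profile_lookup(profile)
  for (k in seq_len(max_tries) - 1L) {
    seg <- withr::with_seed(seed + k, {
      paste(sample(AA20, length, replace = TRUE), collapse = "")
    })
    hits <- scan_one(seg, profile, lookup, min_score = 8L,
                     allow_inverted = TRUE, allow_core_only = TRUE)
    if (nrow(hits) == 0) return(seg)
  }
  abort("could not generate a motif-free segment; increase max_tries")
}

# Fixed stand-in segments shared by the construct panel. The N-alpha
# placeholder is 16 neutral residues (initial Met + glycines) matching the
# length of the natural N-alpha extension without inventing its sequence.
segment_nalpha <- function() paste0("M", strrep("G", 15))
segment_trx_core <- function() motif_free_segment(109, seed = 202L)
segment_gfp <- function() motif_free_segment(120, seed = 101L)

#' Synthetic NaTrxh-like fixture record
#'
#' A 152-residue synthetic protein laid out like the natural extracellular
#' thioredoxin that defined the motif: a 16-residue N-alpha placeholder,
#' the canonical motif at residues 17--27, and a motif-free body. Only the
#' motif and the segment lengths are meaningful; the rest is a seeded random
#' stand-in (hence the `_synthetic` id).
#'
#' @return A one-row record tibble (taxon `plant`, annotated `secreted`,
#'   score 5).
#' @export
#'
#' @examples
#' scan_proteins(natrxh_fixture())
natrxh_fixture <- function() {
  body <- motif_free_segment(125, seed = 303L)
  protein_records(
    id = "NaTrxh_synthetic",
    sequence = paste0(segment_nalpha(), canonical_nbeta(), body),
    description = "synthetic stand-in: canonical motif at residues 17-27",
    taxon = "plant", localisation = "secreted", score = 5L
  )
}

#' The built-in GFP-fusion construct panel
#'
#' The fifteen fusion constructs whose localisation was established by
#' transient expression in onion epidermal cells, rebuilt from synthetic
#' segments: the deletion series (3-residue deletions retain secretion,
#' 6-residue deletions abolish it), the point-variant panel at positions 5,
#' 8 and 9, the placement panel (interior motif fails; motif at the exact
#' C-terminus and the inverted motif secrete), and the ER-retention assay
#' (C-terminal KDEL). Sequence bodies are seeded motif-free stand-ins, so
#' each construct's fate is carried entirely by its motif and placement.
#'
#' @return A tibble with columns `name`, `segments` (display string),
#'   `sequence`, `expected` (observed compartment) and `provenance`.
#' @export
#'
#' @examples
#' evaluate_constructs(paper_constructs())
paper_constructs <- function() {
  nalpha <- segment_nalpha()
  core <- segment_trx_core()
  gfp <- segment_gfp()
  nb <- canonical_nbeta()
  construct <- function(name, segments, expected, provenance) {
    seq <- paste(segments, collapse = "")
    tibble(
      name = name,
      segments = paste(names(segments), collapse = "+"),
      sequence = seq,
      expected = expected,
      provenance = provenance
    )
  }
  bind_rows(
    construct("NaTrxh-GFP",
              c(Nalpha = nalpha, Nbeta = nb, core = core, GFP = gfp),
              "secreted", "full-length control"),
    construct("Nbeta-GFP",
              c(M = "M", Nbeta = nb, GFP = gfp),
              "secreted", "motif-only control"),
    construct("dNalpha3-GFP",
              c(Nbeta_minus3 = nbeta_variant("minus3"), core = core,
                GFP = gfp),
              "secreted", "deletion series"),
    construct("Nbeta_minus3-GFP",
              c(M = "M", Nbeta_minus3 = nbeta_variant("minus3"), GFP = gfp),
              "secreted", "deletion series"),
    construct("dNalpha6-GFP",
              c(Nbeta_minus6 = nbeta_variant("minus6"), core = core,
                GFP = gfp),
              "cytoplasmic", "deletion series"),
    construct("Nbeta_minus6-GFP",
              c(M = "M", Nbeta_minus6 = nbeta_variant("minus6"), GFP = gfp),
              "cytoplasmic", "deletion series"),
    construct("Nbeta_S5G-GFP",
              c(M = "M", Nbeta_S5G = nbeta_variant("S5G"), GFP = gfp),
              "secreted", "point-variant panel"),
    construct("Nbeta_S9A-GFP",
              c(M = "M", Nbeta_S9A = nbeta_variant("S9A"), GFP = gfp),
              "cytoplasmic", "point-variant panel"),
    construct("Nbeta_S8A-GFP",
              c(M = "M", Nbeta_S8A = nbeta_variant("S8A"), GFP = gfp),
              "secreted", "point-variant panel"),
    construct("Nbeta_S8D-GFP",
              c(M = "M", Nbeta_S8D = nbeta_variant("S8D"), GFP = gfp),
              "cytoplasmic", "point-variant panel"),
    construct("Nbeta_S8E-GFP",
              c(M = "M", Nbeta_S8E = nbeta_variant("S8E"), GFP = gfp),
              "cytoplasmic", "point-variant panel"),
    construct("core-Nbeta-GFP_interior",
              c(core = core, Nbeta = nb, GFP = gfp),
              "cytoplasmic", "placement panel"),
    construct("GFP-Nbeta",
              c(GFP = gfp, Nbeta = nb),
              "secreted", "placement panel"),
    construct("Nbeta_inv-GFP",
              c(M = "M", Nbeta_inv = nbeta_variant("inverted"), GFP = gfp),
              "secreted", "placement panel"),
    construct("GFP-Nbeta-KDEL",
              c(GFP = gfp, Nbeta = nb, KDEL = "KDEL"),
              "er_retained", "retention assay")
  )
}

# Valid 0-based start positions placing a window of `len` with its start in
# quarter q0 (0-based quarter index) of a sequence of length L.
quarter_start_range <- function(q0, L, len) {
  lo <- ceiling(q0 * L / 4)
  hi <- ceiling((q0 + 1) * L / 4) - 1
  starts <- seq.int(lo, hi)
  starts[starts + len <= L]
}

#' Simulate a proteome with planted motif variants
#'
#' Generates a seeded random proteome and plants named motif variants at
#' controlled quarters, returning both the records and a truth table. Each
#' planted motif overwrites the background at a start drawn uniformly among
#' the positions whose quarter assignment matches the request (so planted
#' coordinates are exact by construction). Defaults emulate the published
#' survey dataset: 304 proteins, 299 of them carrying the canonical motif
#' with quarter counts 101/65/45/88, and the 266/22/16
#' animal/fungus/plant taxon composition.
#'
#' @param n_sequences Number of proteins.
#' @param length_range Integer min/max sequence length (uniform). The
#'   minimum must leave room to place a motif in any quarter.
#' @param planted A tibble with columns `variant`, `quarter`, `count` and
#'   optional `taxon`, `localisation`, `score` applied to the planted
#'   records. Total count must not exceed `n_sequences`.
#' @param residue_background Named numeric vector of background residue
#'   frequencies over the 20 canonical residues (default uniform; uniform
#'   background maximises the detectability of accidental motif collisions).
#' @param taxon_probs Named probabilities used to draw taxa for records
#'   without an explicit planted taxon.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#'
#' @return A list with elements `records` (a record tibble) and `truth`
#'   (tibble: `id`, `variant`, `start`, `end` 1-based inclusive, `quarter`,
#'   `taxon`, `localisation`, `score`; unplanted records carry `NA`
#'   variant/coordinates).
#' @export
#'
#' @examples
#' sim <- simulate_proteome(n_sequences = 20,
#'                          planted = tibble::tibble(variant = "canonical",
#'                                                   quarter = "P1",
#'                                                   count = 10),
#'                          seed = 7)
#' sim$truth
simulate_proteome <- function(n_sequences = 304,
                              length_range = c(80, 600),
                              planted = default_planting(),
                              residue_background = NULL,
                              taxon_probs = c(plant = 16, animal = 266,
                                              fungus = 22) / 304,
                              seed = 1L) {
  stopifnot(n_sequences >= 1, length(length_range) == 2,
            length_range[1] >= 48, length_range[2] >= length_range[1])
  planted <- as_tibble(planted)
  if (nrow(planted) > 0) {
    stopifnot(all(c("variant", "quarter", "count") %in% names(planted)))
    if (!"taxon" %in% names(planted)) planted$taxon <- NA_character_
    if (!"localisation" %in% names(planted)) {
      planted$localisation <- NA_character_
    }
    if (!"score" %in% names(planted)) planted$score <- NA_integer_
    stopifnot(all(planted$quarter %in% QUARTERS))
  }
  n_planted <- if (nrow(planted) > 0) sum(planted$count) else 0L
  if (n_planted > n_sequences) {
    abort("planted counts exceed n_sequences")
  }
  if (is.null(residue_background)) {
    residue_background <- setNames(rep(1 / 20, 20), AA20)
  }
  stopifnot(abs(sum(residue_background) - 1) < 1e-6,
            all(names(residue_background) %in% AA20))

  withr::with_seed(as.integer(seed), {
    lengths <- sample(length_range[1]:length_range[2], n_sequences,
                      replace = TRUE)
    seqs <- vapply(lengths, function(L) {
      paste(sample(names(residue_background), L, replace = TRUE,
                   prob = residue_background), collapse = "")
    }, character(1))
    taxa <- sample(names(taxon_probs), n_sequences, replace = TRUE,
                   prob = taxon_probs)
    ids <- sprintf("sim%04d", seq_len(n_sequences))

    truth <- tibble(
      id = ids, variant = NA_character_, start = NA_integer_,
      end = NA_integer_, quarter = NA_character_, taxon = taxa,
      localisation = "none", score = 0L
    )

    if (n_planted > 0) {
      plan <- tidyr::uncount(planted, weights = .data$count)
      targets <- sample(n_sequences, n_planted)
      for (k in seq_len(n_planted)) {
        i <- targets[[k]]
        motif <- nbeta_variant(plan$variant[[k]])
        len <- nchar(motif)
        L <- lengths[[i]]
        q0 <- match(plan$quarter[[k]], QUARTERS) - 1L
        starts <- quarter_start_range(q0, L, len)
        if (length(starts) == 0) {
          abort("motif does not fit the requested quarter; sequences too short")
        }
        s0 <- if (length(starts) == 1) starts else sample(starts, 1)
        substr(seqs[[i]], s0 + 1, s0 + len) <- motif
        truth$variant[[i]] <- plan$variant[[k]]
        truth$start[[i]] <- s0 + 1L
        truth$end[[i]] <- s0 + len
        truth$quarter[[i]] <- plan$quarter[[k]]
        if (!is.na(plan$taxon[[k]])) truth$taxon[[i]] <- plan$taxon[[k]]
        if (!is.na(plan$localisation[[k]])) {
          truth$localisation[[i]] <- plan$localisation[[k]]
        }
        if (!is.na(plan$score[[k]])) truth$score[[i]] <- plan$score[[k]]
      }
    }

    records <- protein_records(
      id = ids, sequence = seqs,
      description = ifelse(is.na(truth$variant), "background",
                           paste0("planted:", truth$variant)),
      taxon = truth$taxon, localisation = truth$localisation,
      score = truth$score
    )
    list(records = records, truth = truth)
  })
}

#' Default planting scheme: the published survey's quarter marginals
#'
#' 299 canonical motifs distributed over the quarters as 101/65/45/88 --
#' the printed quarter counts of the motif survey this generator stands in
#' for.
#'
#' @return A planting tibble for [simulate_proteome()].
#' @export
default_planting <- function() {
  tibble(
    variant = "canonical",
    quarter = QUARTERS,
    count = c(101L, 65L, 45L, 88L)
  )
}

#' Synthetic re-encoding of the published survey table
#'
#' Builds a fully synthetic 304-protein dataset whose *marginals* match the
#' published survey: quarter counts 101/65/45/88 over 299 motif-carrying
#' proteins (plus 5 motif-free ones), taxon split 266 animals / 22 fungi /
#' 16 plants, and evidence categories A (8 secreted, score 5, all in P1),
#' B (78 secreted, score 2), C (8 cytoplasmic, score 5, none in P1) and
#' D (210 residual). Sequences are random stand-ins; only placements and
#' annotations are meaningful.
#'
#' @param seed Integer seed.
#' @return As [simulate_proteome()]: a list with `records` and `truth`.
#' @export
simulate_survey_like <- function(seed = 1L) {
  quarter_totals <- c(P1 = 101L, P2 = 65L, P3 = 45L, P4 = 88L)
  slots <- tibble(
    quarter = rep(names(quarter_totals), quarter_totals),
    localisation = "none", score = 0L
  )
  # A: high-evidence secreted, all in the N-terminal quarter.
  a_idx <- which(slots$quarter == "P1")[1:8]
  slots$localisation[a_idx] <- "secreted"
  slots$score[a_idx] <- 5L
  # C: high-evidence cytoplasmic, spread over P2-P4 only.
  c_idx <- c(which(slots$quarter == "P2")[1:3],
             which(slots$quarter == "P3")[1:3],
             which(slots$quarter == "P4")[1:2])
  slots$localisation[c_idx] <- "cytoplasmic"
  slots$score[c_idx] <- 5L
  # B: secreted with intermediate evidence, filling the next free slots.
  free <- which(slots$localisation == "none")
  b_idx <- free[1:78]
  slots$localisation[b_idx] <- "secreted"
  slots$score[b_idx] <- 2L
  # Taxa: exact published split over all 304 records (299 planted + 5 free).
  taxa <- rep(c("plant", "fungus", "animal"), c(16L, 22L, 266L))
  slots$taxon <- taxa[seq_len(nrow(slots))]
  planted <- slots %>%
    count(.data$quarter, .data$taxon, .data$localisation, .data$score,
          name = "count") %>%
    mutate(variant = "canonical")
  sim <- simulate_proteome(
    n_sequences = 304,
    planted = planted,
    taxon_probs = c(animal = 1),
    seed = seed
  )
  # The 5 motif-free records take the remaining taxon slots.
  leftover <- taxa[(nrow(slots) + 1):304]
  free_ids <- sim$truth$id[is.na(sim$truth$variant)]
  idx <- match(free_ids, sim$truth$id)
  sim$truth$taxon[idx] <- leftover
  ridx <- match(free_ids, sim$records$id)
  sim$records$taxon[ridx] <- leftover
  sim
}
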