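#' Per-position residue frequencies of aligned motifs
#'
#' Computes, for a set of equal-length motif strings (e.g. the 11-mer
#' windows extracted by [scan_proteins()]), the relative residue frequency
#' at every position together with its information content in bits --
#' the numbers behind a sequence logo.
#'
#' @param motifs Character vector of equal-length residue strings. `X`
#'   residues are ignored, with renormalisation over the remaining residues
#'   at that position.
#' @return An object of class `nbeta_logo`: a tibble with columns
#'   `position`, `residue`, `frequency`, `bits` (the column's total
#'   information content, repeated within a position).
#' @export
#'
#' @examples
#' logo_columns(c("ES", "EG"))
logo_columns <- function(motifs) {
  motifs <- toupper(motifs)
  if (length(motifs) == 0) abort("no motifs supplied")
  lens <- nchar(motifs)
  if (length(unique(lens)) != 1) abort("motifs must all have the same length")
  width <- lens[[1]]
  mat <- do.call(rbind, strsplit(motifs, ""))
  cols <- purrr::map(seq_len(width), function(p) {
    res <- mat[, p]
    res <- res[res != "X"]
    if (length(res) == 0) {
      abort(paste0("position ", p, " is all-X; frequencies undefined"))
    }
    if (!all(res %in% AA20)) abort("invalid residue in motifs")
    freq <- table(res) / length(res)
    tibble(
      position = p,
      residue = names(freq),
      frequency = as.numeric(freq)
    )
  })
  out <- bind_rows(cols) %>%
    group_by(.data$position) %>%
    mutate(bits = information_content(.data$frequency)) %>%
    ungroup()
  class(out) <- c("nbeta_logo", class(out))
  out
}

#' Information content of a frequency column
#'
#' Information content in bits of one logo column, in the Schneider-Stephens
#' convention for amino acids: `log2(20)` minus the Shannon entropy of the
#' residue frequencies. No small-sample correction is applied.
#'
#' @param frequencies Numeric vector of residue frequencies summing to 1.
#' @return Information content in bits, in `[0, log2(20)]`.
#' @export
#'
#' @examples
#' information_content(1)            # log2(20) = 4.3219...
#' information_content(rep(0.05, 20)) # 0
information_content <- function(frequencies) {
  frequencies <- frequencies[frequencies > 0]
  if (abs(sum(frequencies) - 1) > 1e-6) {
    abort("frequencies must sum to 1")
  }
  entropy <- -sum(frequencies * log2(frequencies))
  log2(20) - entropy
}

#' Consensus string with bracket notation
#'
#' Renders a logo as a consensus string, one token per position: the modal
#' residue when it clearly dominates (frequency at least `wildcard_threshold`
#' and runner-up below 0.2); a two-residue token `"A/B"` when the top two
#' residues jointly reach the threshold and each holds at least 0.2; `"X"`
#' otherwise. Ties are broken alphabetically, so an exact 50/50 E/D column
#' renders `"D/E"`.
#'
#' @param columns An `nbeta_logo` tibble from [logo_columns()].
#' @param wildcard_threshold Dominance threshold (default 0.5).
#' @return A character vector of per-position tokens; collapse with
#'   `paste(..., collapse = "-")` for display.
#' @export
#'
#' @examples
#' consensus_string(logo_columns(c("ES", "ES")))
consensus_string <- function(columns, wildcard_threshold = 0.5) {
  columns <- as_tibble(columns)
  stopifnot(all(c("position", "residue", "frequency") %in% names(columns)))
  positions <- sort(unique(columns$position))
  vapply(positions, function(p) {
    col <- columns[columns$position == p, ]
    col <- col[order(-col$frequency, col$residue), ]
    top1 <- col$frequency[[1]]
    top2 <- if (nrow(col) >= 2) col$frequency[[2]] else 0
    if (top1 >= wildcard_threshold && top2 < 0.2) {
      col$residue[[1]]
    } else if (top1 + top2 >= wildcard_threshold &&
               top1 >= 0.2 && top2 >= 0.2) {
      paste(sort(col$residue[1:2]), collapse = "/")
    } else {
      "X"
    }
  }, character(1))
}

#' Sequence-logo style plot of a frequency table
#'
#' Stacked-letter logo: at each position, residues are stacked with heights
#' proportional to `frequency * bits`, the standard information-content
#' scaling of sequence logos.
#'
#' @param object An `nbeta_logo` tibble from [logo_columns()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nbeta_logo <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(height = .data$frequency * .data$bits) %>%
    arrange(.data$position, .data$height) %>%
    group_by(.data$position) %>%
    mutate(ymax = cumsum(.data$height),
           ymin = .data$ymax - .data$height,
           ymid = (.data$ymin + .data$ymax) / 2) %>%
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$position - 0.45,
                   xmax = .data$position + 0.45,
                   ymin = .data$ymin, ymax = .data$ymax,
                   fill = .data$residue),
      colour = "white", linewidth = 0.2, show.legend = FALSE
    ) +
    ggplot2::geom_text(
      ggplot2::aes(y = .data$ymid, label = .data$residue,
                   size = .data$height),
      colour = "grey10", show.legend = FALSE
    ) +
    ggplot2::scale_size(range = c(1, 6)) +
    ggplot2::scale_x_continuous(breaks = sort(unique(df$position))) +
    ggplot2::labs(x = "motif position", y = "information (bits)") +
    ggplot2::theme_minimal()
}

#' Bar plot of the quartile distribution
#'
#' @param object An `nbeta_quartiles` tibble from [quartile_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nbeta_quartiles <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$quarter, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_hline(yintercept = sum(df$n) / 4, linetype = "dashed") +
    ggplot2::labs(x = "quarter of the primary structure",
                  y = "proteins with the motif") +
    ggplot2::theme_minimal()
}
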