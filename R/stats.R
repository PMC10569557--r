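#' Assign localisation-evidence categories
#'
#' Bins annotated proteins into the four evidence categories used for the
#' dataset-level analysis: **A** secreted with evidence score 5, **B**
#' secreted with score strictly between 1 and 3, **C** cytoplasmic with
#' score 5, and **D** everything else (no annotation, other compartments,
#' or secreted with intermediate score 3--4). The partition is total and
#' exclusive: every record lands in exactly one category.
#'
#' @param records A record tibble carrying `localisation` and `score`.
#' @return A tibble with columns `id`, `category`.
#' @export
#'
#' @examples
#' assign_categories(protein_records("p", "MAESG", localisation = "secreted",
#'                                   score = 5))
assign_categories <- function(records) {
  records <- validate_records(records)
  category <- dplyr::case_when(
    records$localisation == "secreted" & records$score == 5 ~ "A",
    records$localisation == "secreted" &
      records$score > 1 & records$score < 3 ~ "B",
    records$localisation == "cytoplasmic" & records$score == 5 ~ "C",
    TRUE ~ "D"
  )
  tibble(id = records$id, category = category)
}

#' Category percentages
#'
#' Percentage of proteins in each category, reported to two decimals.
#'
#' @param assignments A tibble with a `category` column (as from
#'   [assign_categories()]), or a character vector of categories.
#' @return A tibble with columns `category`, `n`, `percent`; all four
#'   categories are always present (zero counts included).
#' @export
category_percentages <- function(assignments) {
  categories <- if (is.data.frame(assignments)) {
    assignments$category
  } else {
    as.character(assignments)
  }
  if (length(categories) == 0) abort("no category assignments supplied")
  counts <- table(factor(categories, levels = c("A", "B", "C", "D")))
  tibble(
    category = names(counts),
    n = as.integer(counts),
    percent = round(100 * as.integer(counts) / length(categories), 2)
  )
}

#' Quartile distribution of motif placements
#'
#' Counts, over one best match per protein, how many motifs start in each
#' quarter of the primary structure. Proteins without a match are excluded
#' from the counts and reported in the `n_excluded` attribute.
#'
#' @param calls A tibble with columns `id` and `quarter` (e.g. the output of
#'   [predict_localisation()] or [scan_proteins()] reduced to one row per
#'   protein).
#' @return An object of class `nbeta_quartiles`: a tibble with columns
#'   `quarter` (`P1`--`P4`) and `n`, with attributes `total` and
#'   `n_excluded`.
#' @export
quartile_distribution <- function(calls) {
  calls <- as_tibble(calls)
  stopifnot(all(c("id", "quarter") %in% names(calls)))
  if (anyDuplicated(calls$id)) {
    abort("expected one (best) match per protein; duplicated id found")
  }
  excluded <- is.na(calls$quarter)
  quarters <- calls$quarter[!excluded]
  counts <- table(factor(quarters, levels = QUARTERS))
  out <- tibble(quarter = QUARTERS, n = as.integer(counts))
  attr(out, "total") <- sum(out$n)
  attr(out, "n_excluded") <- sum(excluded)
  class(out) <- c("nbeta_quartiles", class(out))
  out
}

#' Chi-square goodness of fit against a uniform quartile distribution
#'
#' Pearson chi-square test of the observed quarter counts against the
#' uniform null (one quarter of the motifs in each of the four equal parts),
#' with 3 degrees of freedom and an upper-tail p-value.
#'
#' @param counts An `nbeta_quartiles` tibble from [quartile_distribution()],
#'   a data frame with columns `quarter`/`n`, or a plain numeric vector of
#'   four counts.
#' @return An object of class `nbeta_chisq` with elements `statistic`, `df`,
#'   `p.value`, `observed`, `expected`. [tidy()]/[glance()] return it as a
#'   one-row tibble.
#' @export
#'
#' @examples
#' chi_square_uniform(c(101, 65, 45, 88))
chi_square_uniform <- function(counts) {
  obs <- if (is.data.frame(counts)) counts$n else as.numeric(counts)
  if (length(obs) != 4 || any(obs < 0)) {
    abort("expected four non-negative quarter counts")
  }
  total <- sum(obs)
  if (total <= 0) abort("total count is zero")
  expected <- rep(total / 4, 4)
  statistic <- sum((obs - expected)^2 / expected)
  df <- 3L
  out <- list(
    statistic = statistic,
    df = df,
    p.value = pchisq(statistic, df = df, lower.tail = FALSE),
    observed = obs,
    expected = expected
  )
  class(out) <- "nbeta_chisq"
  out
}

#' @export
print.nbeta_chisq <- function(x, ...) {
  cat("Chi-square goodness of fit vs uniform quarters\n")
  cat("  X-squared = ", format(x$statistic, digits = 5),
      ", df = ", x$df,
      ", p-value = ", format(signif(x$p.value, 4)), "\n", sep = "")
  invisible(x)
}

#' @rdname chi_square_uniform
#' @param x An `nbeta_chisq` object.
#' @param ... Unused.
#' @export
tidy.nbeta_chisq <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    df = x$df,
    p.value = signif(x$p.value, 4),
    total = sum(x$observed)
  )
}

#' @rdname chi_square_uniform
#' @export
glance.nbeta_chisq <- function(x, ...) {
  tidy(x)
}

#' Cross-tabulate categories (or functions) against quarters
#'
#' Builds the category-by-quarter contingency table and evaluates the
#' headline positional contrast: are all category-A (high-evidence secreted)
#' motifs in the N-terminal quarter, and no category-C (high-evidence
#' cytoplasmic) motif in it?
#'
#' @param assignments A tibble with columns `id` and a grouping column
#'   (default `category`), as from [assign_categories()].
#' @param calls A tibble with columns `id` and `quarter` (one row per
#'   protein); rows with `NA` quarter (no motif) are dropped.
#' @param group Name of the grouping column in `assignments`
#'   (default `"category"`; pass e.g. `"function"` for a function-by-quarter
#'   table).
#' @return A tibble in wide form (one row per group, one column per quarter)
#'   with attributes `a_all_in_p1` and `c_none_in_p1` (logical, `NA` when
#'   the corresponding category is absent).
#' @export
crosstab_quarters <- function(assignments, calls, group = "category") {
  assignments <- as_tibble(assignments)
  calls <- as_tibble(calls)
  stopifnot(group %in% names(assignments), "id" %in% names(assignments),
            all(c("id", "quarter") %in% names(calls)))
  calls <- filter(calls, !is.na(.data$quarter))
  joined <- dplyr::inner_join(
    select(assignments, "id", dplyr::all_of(group)),
    select(calls, "id", "quarter"),
    by = "id"
  )
  if (nrow(joined) == 0) {
    abort(paste0(
      "no protein ids shared between assignments and calls; unmatched: ",
      paste(head(setdiff(assignments$id, calls$id), 5), collapse = ", ")
    ))
  }
  joined$.group <- joined[[group]]
  tab <- joined %>%
    count(.data$.group, quarter = factor(.data$quarter, levels = QUARTERS),
          .drop = FALSE) %>%
    tidyr::pivot_wider(names_from = "quarter", values_from = "n",
                       values_fill = 0L) %>%
    rename(!!group := ".group")
  if (group == "category" && "A" %in% tab$category) {
    a_row <- tab[tab$category == "A", QUARTERS]
    attr(tab, "a_all_in_p1") <- a_row$P1 == sum(unlist(a_row))
  } else {
    attr(tab, "a_all_in_p1") <- NA
  }
  if (group == "category" && "C" %in% tab$category) {
    attr(tab, "c_none_in_p1") <- tab$P1[tab$category == "C"] == 0L
  } else {
    attr(tab, "c_none_in_p1") <- NA
  }
  tab
}
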