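#' Rachis-versus-edge intensity ratio with background correction
#'
#' Computes, per animal, the ratio of background-corrected mean intensity
#' in the rachis (central cytoplasmic core of the germ line) to the summed
#' background-corrected intensity of the two germline-edge ROIs:
#'
#' \deqn{\frac{2(\mathrm{rachis} - \mathrm{bg})}{\mathrm{edge}_1 +
#'   \mathrm{edge}_2 - 2\,\mathrm{bg}}}
#'
#' The default `"symmetric"` mode subtracts the background from the rachis
#' term twice (matching the doubled rachis measurement), which makes the
#' ratio invariant under any affine intensity transform `v -> a*v + b`
#' (detector gain and baseline offset). The `"literal"` mode subtracts it
#' once from the numerator (`(2*rachis - bg) / (edge1 + edge2 - 2*bg)`);
#' being a ratio of intensity-linear forms it still tolerates pure
#' rescaling, but a baseline offset changes its value. Records whose
#' denominator is not positive get `NA` with `flagged = TRUE` and are
#' excluded from group aggregates.
#'
#' @param measurements Data frame with columns `animal_id`, `rachis`,
#'   `edge1`, `edge2`, `background` (ROI mean gray values, >= 0); an
#'   optional `genotype` column is carried through.
#' @param mode `"symmetric"` (default) or `"literal"`.
#'
#' @return The input as a tibble with added columns `ratio` and `flagged`.
#' @examples
#' m <- tibble::tibble(animal_id = "a1", rachis = 50,
#'                     edge1 = 80, edge2 = 60, background = 10)
#' rachis_edge_ratio(m)   # 80 / 120 = 0.6667
#' @export
rachis_edge_ratio <- function(measurements, mode = c("symmetric", "literal")) {
  mode <- match.arg(mode)
  need <- c("animal_id", "rachis", "edge1", "edge2", "background")
  if (!is.data.frame(measurements) || !all(need %in% names(measurements))) {
    stop_config(sprintf("`measurements` needs columns %s.",
                        paste(need, collapse = ", ")))
  }
  vals <- measurements[c("rachis", "edge1", "edge2", "background")]
  if (anyNA(vals) || any(vals < 0)) {
    stop_value("ROI intensities must be nonnegative and non-missing.")
  }
  out <- as_tibble(measurements)
  denom <- out$edge1 + out$edge2 - 2 * out$background
  numer <- if (mode == "symmetric") {
    2 * (out$rachis - out$background)
  } else {
    2 * out$rachis - out$background
  }
  flagged <- denom <= 0
  out$ratio <- ifelse(flagged, NA_real_, numer / denom)
  out$flagged <- flagged
  if (any(flagged)) {
    warn(sprintf(
      "%d record(s) with nonpositive denominator flagged and excluded.",
      sum(flagged)
    ))
  }
  out
}

#' Summarise rachis/edge ratios per genotype with pairwise t-tests
#'
#' Groups per-animal ratios by genotype and compares every pair of
#' genotypes with a two-tailed pooled-variance Student t-test (flagged
#' records are excluded first). Pairs where either group has fewer than 2
#' defined ratios are skipped with a warning.
#'
#' @param ratios Output of [rachis_edge_ratio()]; must contain a
#'   `genotype` column (or supply `group_of`).
#' @param group_of Optional named vector mapping `animal_id` to genotype,
#'   used when `ratios` has no `genotype` column.
#'
#' @return An object of class `"roi_summary"`: a list with `groups`
#'   (tibble of per-genotype n, mean, sd, median) and `tests` (tibble of
#'   pairwise two-tailed p-values). [tidy()] returns the pairwise tests,
#'   [glance()] the group table, [autoplot()] the boxplot.
#' @export
ratio_summary <- function(ratios, group_of = NULL) {
  if (!"genotype" %in% names(ratios)) {
    if (is.null(group_of)) {
      stop_config("Provide a `genotype` column or a `group_of` mapping.")
    }
    ratios$genotype <- unname(group_of[as.character(ratios$animal_id)])
  }
  if (!"ratio" %in% names(ratios)) {
    stop_config("`ratios` must come from rachis_edge_ratio().")
  }
  ok <- ratios[!ratios$flagged & !is.na(ratios$ratio), , drop = FALSE]
  groups <- as_tibble(ok) |>
    group_by(.data$genotype) |>
    summarise(
      n = dplyr::n(),
      mean = mean(.data$ratio),
      sd = stats::sd(.data$ratio),
      median = median(.data$ratio),
      ratios = list(.data$ratio),
      .groups = "drop"
    ) |>
    arrange(.data$genotype)
  pairs <- if (nrow(groups) >= 2) utils::combn(groups$genotype, 2) else
    matrix(character(), nrow = 2)
  tests <- purrr::map(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]
    g2 <- pairs[2, i]
    x <- groups$ratios[[match(g1, groups$genotype)]]
    y <- groups$ratios[[match(g2, groups$genotype)]]
    if (length(x) < 2L || length(y) < 2L) {
      warn(sprintf("Skipping pair %s vs %s: fewer than 2 ratios.", g1, g2))
      return(NULL)
    }
    tt <- pooled_t_test(x, y, tail = "two-sided")
    tibble(group1 = g1, group2 = g2, statistic = tt$statistic,
           df = tt$df, p_value = tt$p_value, degenerate = tt$degenerate)
  }) |>
    bind_rows()
  structure(
    list(groups = groups, tests = tests,
         n_flagged = sum(ratios$flagged)),
    class = "roi_summary"
  )
}

#' @export
print.roi_summary <- function(x, ...) {
  cat("Rachis/edge ratio summary\n")
  print(x$groups |> select(!"ratios"))
  if (nrow(x$tests)) {
    cat("Pairwise two-tailed t-tests:\n")
    print(x$tests)
  }
  invisible(x)
}

#' @export
tidy.roi_summary <- function(x, ...) {
  x$tests
}

#' @export
glance.roi_summary <- function(x, ...) {
  x$groups |> select(!"ratios")
}
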