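#' Configuration for spectral-count enrichment calling
#'
#' Bundles the thresholds and model switches used by [call_enrichment()].
#' Defaults reproduce the standard proximity-labeling screen: a pseudo-count
#' of 0.01 on the group means, a one-tailed pooled-variance (Student)
#' t-test against the untagged control, and calls at log2 fold change >= 3
#' (fold change >= 8) with raw p < 0.05.
#'
#' @param pseudo_count Constant added to both group means before forming the
#'   fold-change ratio, so the ratio is defined when the control mean is
#'   zero. Must be > 0.
#' @param min_log2fc Inclusive log2 fold-change threshold for the enriched
#'   flag. Must be >= 0.
#' @param alpha Strict p-value threshold for the enriched flag, in (0, 1).
#' @param tail Alternative hypothesis for the t-test: `"greater"` (bait >
#'   control, the default), `"less"`, or `"two-sided"`.
#' @param variance_model `"pooled"` (equal-variance Student, default) or
#'   `"welch"`.
#' @param p_adjust `"none"` (default; the enriched flag always uses raw p)
#'   or `"benjamini-hochberg"` to emit an extra adjusted column.
#' @param pseudo_count_scope `"fold-change-only"` (default: the t-test runs
#'   on raw replicate counts) or `"fold-change-and-test"` (the pseudo-count
#'   is also added to every count before testing).
#'
#' @return A list of class `"enrichment_config"`.
#' @examples
#' enrichment_config()
#' enrichment_config(alpha = 0.01, p_adjust = "benjamini-hochberg")
#' @export
enrichment_config <- function(pseudo_count = 0.01,
                              min_log2fc = 3,
                              alpha = 0.05,
                              tail = c("greater", "less", "two-sided"),
                              variance_model = c("pooled", "welch"),
                              p_adjust = c("none", "benjamini-hochberg"),
                              pseudo_count_scope = c("fold-change-only",
                                                     "fold-change-and-test")) {
  check_scalar_number(pseudo_count, "pseudo_count", min = 0, strict_min = TRUE)
  check_scalar_number(min_log2fc, "min_log2fc", min = 0)
  check_scalar_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  if (alpha >= 1) stop_value("`alpha` must be in (0, 1).")
  structure(
    list(
      pseudo_count = pseudo_count,
      min_log2fc = min_log2fc,
      alpha = alpha,
      tail = match.arg(tail),
      variance_model = match.arg(variance_model),
      p_adjust = match.arg(p_adjust),
      pseudo_count_scope = match.arg(pseudo_count_scope)
    ),
    class = "enrichment_config"
  )
}

# Validates the counts + sample-sheet pair and returns the numeric count
# matrix (proteins x samples) with sample columns in sheet order.
validate_counts <- function(counts, samples) {
  if (!is.data.frame(counts) || !"protein_id" %in% names(counts)) {
    stop_config("`counts` must be a data frame with a `protein_id` column.")
  }
  if (!is.data.frame(samples) ||
      !all(c("sample_id", "group") %in% names(samples))) {
    stop_config("`samples` must have columns `sample_id` and `group`.")
  }
  if (anyDuplicated(counts$protein_id)) {
    stop_config("`protein_id` values must be unique.")
  }
  bad_group <- setdiff(unique(samples$group), c("bait", "control"))
  if (length(bad_group)) {
    stop_config(sprintf("Unknown group label(s): %s.",
                        paste(bad_group, collapse = ", ")))
  }
  missing_cols <- setdiff(samples$sample_id, names(counts))
  if (length(missing_cols)) {
    stop_config(sprintf("Sample(s) missing from the counts table: %s.",
                        paste(missing_cols, collapse = ", ")))
  }
  tab <- table(factor(samples$group, levels = c("bait", "control")))
  if (any(tab < 2L)) {
    stop_config("Each group needs at least 2 samples.")
  }
  mat <- as.matrix(counts[, samples$sample_id, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat) || any(mat < 0)) {
    stop_config("Counts must be nonnegative and non-missing.")
  }
  rownames(mat) <- counts$protein_id
  mat
}

#' Per-protein group means of spectral counts
#'
#' Computes the arithmetic mean spectral count over the bait-group and
#' control-group replicates for every protein.
#'
#' @param counts Data frame with a `protein_id` column followed by one
#'   numeric column per sample (nonnegative spectral counts).
#' @param samples Sample sheet: data frame with columns `sample_id`,
#'   `group` (`"bait"` or `"control"`) and optionally `replicate`.
#'
#' @return A tibble with columns `protein_id`, `mean_bait`, `mean_control`,
#'   sorted by `protein_id`.
#' @examples
#' counts <- tibble::tibble(protein_id = "pgl-1",
#'                          b1 = 2, b2 = 4, b3 = 6,
#'                          c1 = 1, c2 = 1, c3 = 1)
#' samples <- tibble::tibble(sample_id = c("b1", "b2", "b3", "c1", "c2", "c3"),
#'                           group = rep(c("bait", "control"), each = 3))
#' group_means(counts, samples)
#' @export
group_means <- function(counts, samples) {
  mat <- validate_counts(counts, samples)
  bait <- mat[, samples$sample_id[samples$group == "bait"], drop = FALSE]
  ctrl <- mat[, samples$sample_id[samples$group == "control"], drop = FALSE]
  tibble(
    protein_id = rownames(mat),
    mean_bait = unname(rowMeans(bait)),
    mean_control = unname(rowMeans(ctrl))
  ) |>
    arrange(.data$protein_id)
}

#' Pseudo-count fold change
#'
#' Fold change between bait and control means with a pseudo-count `c` added
#' to both, `(mean_bait + c) / (mean_control + c)`, so the ratio stays
#' finite when the control mean is zero. Vectorised over the means.
#'
#' @param mean_bait,mean_control Nonnegative mean spectral counts
#'   (recycled to a common length).
#' @param pseudo_count Positive pseudo-count, default 0.01.
#'
#' @return A tibble with columns `fold_change` and `log2fc`.
#' @examples
#' fold_change(1, 0)            # control mean of zero: FC = 101
#' fold_change(8, 1)            # raw ratio 8 lands just under log2fc = 3
#' @export
fold_change <- function(mean_bait, mean_control, pseudo_count = 0.01) {
  check_scalar_number(pseudo_count, "pseudo_count", min = 0, strict_min = TRUE)
  if (anyNA(mean_bait) || anyNA(mean_control) ||
      any(mean_bait < 0) || any(mean_control < 0)) {
    stop_value("Group means must be nonnegative and non-missing.")
  }
  fc <- (mean_bait + pseudo_count) / (mean_control + pseudo_count)
  tibble(fold_change = fc, log2fc = log2(fc))
}

# Row-wise two-sample t-test on matrices (proteins x replicates).
# Returns statistic, df, p and a degenerate flag. Zero pooled variance is
# resolved by the limit of the t statistic: equal means -> p = 1;
# a difference in the alternative's direction -> p ~ 0 (stored as 1e-300).
row_t_test <- function(bait, ctrl, tail = "greater",
                       variance_model = "pooled") {
  n1 <- ncol(bait)
  n2 <- ncol(ctrl)
  if (n1 < 2L || n2 < 2L) {
    stop_value("Each group needs at least 2 replicates for a t-test.")
  }
  m1 <- rowMeans(bait)
  m2 <- rowMeans(ctrl)
  v1 <- rowSums((bait - m1)^2) / (n1 - 1)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1)
  if (variance_model == "pooled") {
    df <- rep.int(n1 + n2 - 2, length(m1))
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se2 <- v1 / n1 + v2 / n2
    se <- sqrt(se2)
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
    df[se == 0] <- n1 + n2 - 2
  }
  delta <- m1 - m2
  stat <- delta / se
  degenerate <- se == 0
  stat[degenerate & delta == 0] <- 0
  stat[degenerate & delta > 0] <- Inf
  stat[degenerate & delta < 0] <- -Inf
  p <- switch(tail,
    greater = pt(stat, df, lower.tail = FALSE),
    less = pt(stat, df, lower.tail = TRUE),
    `two-sided` = 2 * pt(abs(stat), df, lower.tail = FALSE)
  )
  # limits of the t statistic for the zero-variance records: no
  # difference -> p = 1; a difference with zero spread -> p ~ 0
  p[degenerate & delta == 0] <- 1
  p[degenerate & p == 0] <- 1e-300
  tibble(statistic = unname(stat), df = unname(df), p_value = unname(p),
         degenerate = unname(degenerate))
}

#' Two-sample Student t-test for replicate spectral counts
#'
#' Pooled-variance (default) or Welch two-sample t-test, with the
#' degenerate zero-variance cases resolved explicitly: when the pooled
#' standard deviation is zero, a zero mean difference gives p = 1 and a
#' difference in the direction of the alternative gives p ~ 0 (reported as
#' 1e-300) with `degenerate = TRUE`.
#'
#' @param bait,control Numeric vectors (one protein) or matrices with one
#'   row per protein and one column per replicate; each needs >= 2 columns.
#' @param tail `"greater"` (default), `"less"` or `"two-sided"`.
#' @param variance_model `"pooled"` (default) or `"welch"`.
#'
#' @return A tibble with columns `statistic`, `df`, `p_value`, `degenerate`.
#' @examples
#' pooled_t_test(c(10, 12, 11), c(1, 2, 1))
#' pooled_t_test(c(5, 5, 5), c(5, 5, 5))   # degenerate: p = 1
#' @export
pooled_t_test <- function(bait, control,
                          tail = c("greater", "less", "two-sided"),
                          variance_model = c("pooled", "welch")) {
  tail <- match.arg(tail)
  variance_model <- match.arg(variance_model)
  if (is.vector(bait)) bait <- matrix(bait, nrow = 1)
  if (is.vector(control)) control <- matrix(control, nrow = 1)
  row_t_test(bait, control, tail = tail, variance_model = variance_model)
}

#' Call enriched proteins from replicate spectral counts
#'
#' Per protein: group means, pseudo-count fold change, one-tailed Student
#' t-test against the control, and an `enriched` flag at
#' `log2fc >= min_log2fc` (inclusive) and `p_value < alpha` (strict).
#' Proteins absent in a sample must be encoded as count 0, not `NA`.
#'
#' @inheritParams group_means
#' @param config An [enrichment_config()].
#'
#' @return A tibble of class `"enrichment_tbl"`, one row per protein sorted
#'   by `protein_id`, with columns `protein_id`, `mean_bait`,
#'   `mean_control`, `fold_change`, `log2fc`, `p_value`, `p_adjusted`,
#'   `neg_log10_p`, `degenerate`, `enriched`. The configuration is attached
#'   as attribute `"config"`; [glance()] summarises the call, [autoplot()]
#'   draws the volcano plot.
#' @examples
#' spec <- simulation_spec(seed = 1, n_proteins = 200, n_enriched = 10)
#' sim <- simulate_counts(spec)
#' res <- call_enrichment(sim$counts, sim$samples)
#' glance(res)
#' @export
call_enrichment <- function(counts, samples, config = enrichment_config()) {
  if (!inherits(config, "enrichment_config")) {
    stop_config("`config` must be created by enrichment_config().")
  }
  mat <- validate_counts(counts, samples)
  bait <- mat[, samples$sample_id[samples$group == "bait"], drop = FALSE]
  ctrl <- mat[, samples$sample_id[samples$group == "control"], drop = FALSE]
  if (config$pseudo_count_scope == "fold-change-and-test") {
    bait_t <- bait + config$pseudo_count
    ctrl_t <- ctrl + config$pseudo_count
  } else {
    bait_t <- bait
    ctrl_t <- ctrl
  }
  tt <- row_t_test(bait_t, ctrl_t, tail = config$tail,
                   variance_model = config$variance_model)
  fc <- fold_change(rowMeans(bait), rowMeans(ctrl), config$pseudo_count)
  out <- tibble(
    protein_id = rownames(mat),
    mean_bait = unname(rowMeans(bait)),
    mean_control = unname(rowMeans(ctrl)),
    fold_change = fc$fold_change,
    log2fc = fc$log2fc,
    p_value = tt$p_value,
    p_adjusted = if (config$p_adjust == "benjamini-hochberg") {
      stats::p.adjust(tt$p_value, method = "BH")
    } else {
      NA_real_
    },
    neg_log10_p = -log10(tt$p_value),
    degenerate = tt$degenerate,
    enriched = fc$log2fc >= config$min_log2fc & tt$p_value < config$alpha
  ) |>
    arrange(.data$protein_id)
  structure(out, class = c("enrichment_tbl", class(out)), config = config)
}

#' Extract the enriched protein identifiers from an enrichment table
#'
#' @param x An `"enrichment_tbl"` from [call_enrichment()].
#' @return Character vector of enriched `protein_id`s, sorted.
#' @export
enriched_ids <- function(x) {
  stopifnot(is.data.frame(x), all(c("protein_id", "enriched") %in% names(x)))
  sort(x$protein_id[x$enriched])
}

#' Intersect two enriched candidate sets
#'
#' Exact set algebra between the candidate lists of two baits, as drawn in
#' a two-set Venn diagram.
#'
#' @param enriched_a,enriched_b Character vectors of protein identifiers
#'   (duplicates are ignored).
#' @return A one-row tibble with columns `only_a`, `only_b`, `both`,
#'   `union` (`union = only_a + only_b + both`).
#' @examples
#' intersect_enrichment(c("glh-1", "pgl-1", "znfx-1"), c("znfx-1", "deps-1"))
#' @export
intersect_enrichment <- function(enriched_a, enriched_b) {
  a <- unique(as.character(enriched_a))
  b <- unique(as.character(enriched_b))
  both <- length(intersect(a, b))
  tibble(
    only_a = length(a) - both,
    only_b = length(b) - both,
    both = both,
    union = length(union(a, b))
  )
}

#' @export
glance.enrichment_tbl <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_proteins = nrow(x),
    n_enriched = sum(x$enriched),
    n_degenerate = sum(x$degenerate),
    pseudo_count = cfg$pseudo_count,
    min_log2fc = cfg$min_log2fc,
    alpha = cfg$alpha,
    tail = cfg$tail,
    variance_model = cfg$variance_model
  )
}

#' @export
tidy.enrichment_tbl <- function(x, ...) {
  as_tibble(x)
}
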