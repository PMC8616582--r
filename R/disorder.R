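#' Keep the longest isoform per gene
#'
#' Collapses an isoform-level table to one record per gene, keeping the
#' isoform with the most residues. Length ties are broken by the
#' lexicographically smallest isoform identifier. Records with zero length
#' (empty sequence) are dropped with a warning.
#'
#' @param isoforms Data frame with columns `gene`, `isoform` and `length`
#'   (residues), e.g. from [read_proteome_fasta()].
#'
#' @return A tibble with one row per gene, sorted by gene.
#' @examples
#' iso <- tibble::tibble(gene = c("glh-1", "glh-1", "pgl-1"),
#'                       isoform = c("glh-1a", "glh-1b", "pgl-1a"),
#'                       length = c(300, 450, 200))
#' longest_isoforms(iso)
#' @export
longest_isoforms <- function(isoforms) {
  if (!is.data.frame(isoforms) ||
      !all(c("gene", "isoform", "length") %in% names(isoforms))) {
    stop_config("`isoforms` needs columns `gene`, `isoform`, `length`.")
  }
  empty <- isoforms$length <= 0 | is.na(isoforms$length)
  if (any(empty)) {
    warn(sprintf("Dropping %d record(s) with empty sequence.", sum(empty)))
    isoforms <- isoforms[!empty, , drop = FALSE]
  }
  as_tibble(isoforms) |>
    arrange(.data$gene, dplyr::desc(.data$length), .data$isoform) |>
    group_by(.data$gene) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$gene)
}

#' Read a proteome FASTA into an isoform table
#'
#' Parses FASTA headers into gene and isoform identifiers with a
#' configurable regular expression, returning the isoform-level table
#' consumed by [longest_isoforms()]. Requires the Biostrings package.
#'
#' @param path FASTA file of protein sequences.
#' @param gene_pattern Regular expression with one capture group applied
#'   to the record name to extract the gene id; the default strips a
#'   trailing isoform letter suffix (`"abc-1a"` -> `"abc-1"`).
#'
#' @return A tibble with columns `gene`, `isoform`, `length`.
#' @export
read_proteome_fasta <- function(path, gene_pattern = "^(.*?)[a-z]?$") {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop_config("read_proteome_fasta() requires the Biostrings package.")
  }
  seqs <- Biostrings::readAAStringSet(path)
  iso <- sub("\\s.*$", "", names(seqs))
  tibble(
    gene = sub(gene_pattern, "\\1", iso),
    isoform = iso,
    length = Biostrings::width(seqs)
  )
}

#' Summarize per-residue disorder scores per protein
#'
#' Aggregates long-format per-residue disorder scores (one row per
#' residue, each score in `[0, 1]`; higher = more disordered) into the
#' per-protein summary: residue count `length`, `total` score and
#' `mean = total / length`.
#'
#' @param scores Data frame with columns `protein_id`, `position`
#'   (1-based) and `score`. Positions must be exactly `1..L` per protein;
#'   files with missing positions are rejected, not imputed.
#'
#' @return A tibble with columns `protein_id`, `length`, `total`, `mean`,
#'   sorted by `protein_id`.
#' @examples
#' sc <- tibble::tibble(protein_id = "x", position = 1:3,
#'                      score = c(0.2, 0.4, 0.9))
#' summarize_disorder(sc)   # mean 0.5
#' @export
summarize_disorder <- function(scores) {
  if (!is.data.frame(scores) ||
      !all(c("protein_id", "position", "score") %in% names(scores))) {
    stop_config("`scores` needs columns `protein_id`, `position`, `score`.")
  }
  if (nrow(scores) == 0L) {
    stop_value("Empty score table.")
  }
  if (anyNA(scores$score) || any(scores$score < 0) || any(scores$score > 1)) {
    stop_value("Disorder scores must lie in [0, 1].")
  }
  out <- as_tibble(scores) |>
    group_by(.data$protein_id) |>
    summarise(
      length = dplyr::n(),
      total = sum(.data$score),
      mean = .data$total / .data$length,
      contiguous = all(sort(.data$position) == seq_len(dplyr::n())),
      .groups = "drop"
    )
  if (!all(out$contiguous)) {
    bad <- out$protein_id[!out$contiguous]
    stop_value(sprintf("Missing/duplicated residue positions for: %s.",
                       paste(utils::head(bad, 5), collapse = ", ")))
  }
  out |>
    select(!"contiguous") |>
    arrange(.data$protein_id)
}

#' Compare a target set's mean disorder against a random control
#'
#' Draws a size-matched control set of proteins uniformly without
#' replacement from the proteome summary (by default excluding the target
#' proteins from the pool) and compares mean disorder between target and
#' control with [wilcoxon_rank_sum()]. The draw is fully determined by
#' `seed`; with `n_draws > 1` the reported p-value is the median across
#' draws and every per-draw result is kept.
#'
#' @param summaries Per-protein disorder summary with columns `protein_id`
#'   and `mean` (from [summarize_disorder()] or a deposited summary file).
#' @param target_ids Character vector of target protein identifiers; at
#'   least 2 must be present in `summaries`.
#' @param seed Integer seed (mandatory; every control draw derives from it).
#' @param n_draws Number of independent control draws (default 1).
#' @param alternative Passed to [wilcoxon_rank_sum()]; default two-sided.
#' @param exclude_targets If `TRUE` (default) target proteins cannot be
#'   sampled into their own control; `FALSE` restores naive whole-proteome
#'   sampling.
#'
#' @return An object of class `"disorder_comparison"`: a list with
#'   `target_n`, `control_n`, `statistic`, `p_value`, `medians` (named pair
#'   of group medians), `alternative`, `seed`, `n_draws`, and a `draws`
#'   tibble with per-draw statistics and control ids. [tidy()] returns the
#'   per-draw table, [glance()] the one-row summary, [autoplot()] the
#'   boxplot.
#' @examples
#' spec <- simulation_spec(seed = 3, n_proteins = 120, n_enriched = 20)
#' sim <- simulate_disorder(spec)
#' cmp <- compare_to_random(sim$summaries, sim$target_ids, seed = 3)
#' glance(cmp)
#' @export
compare_to_random <- function(summaries, target_ids, seed,
                              n_draws = 1,
                              alternative = c("two-sided", "greater", "less"),
                              exclude_targets = TRUE) {
  alternative <- match.arg(alternative)
  if (!is.data.frame(summaries) ||
      !all(c("protein_id", "mean") %in% names(summaries))) {
    stop_config("`summaries` needs columns `protein_id` and `mean`.")
  }
  check_scalar_number(seed, "seed")
  check_scalar_number(n_draws, "n_draws", min = 1)
  target_ids <- unique(as.character(target_ids))
  in_target <- summaries$protein_id %in% target_ids
  target_vals <- summaries$mean[in_target]
  if (length(target_vals) < 2L) {
    stop_value("Fewer than 2 target proteins found in `summaries`.")
  }
  pool <- if (exclude_targets) summaries[!in_target, ] else summaries
  if (nrow(pool) < length(target_vals)) {
    stop_value("Sampling pool smaller than the target set.")
  }
  draws <- purrr::map(seq_len(n_draws), function(d) {
    sub_seed <- derive_seed(seed, paste0("disorder-control-", d))
    ctrl_idx <- with_seed_local(sub_seed,
      sample.int(nrow(pool), length(target_vals))
    )
    ctrl_vals <- pool$mean[ctrl_idx]
    w <- wilcoxon_rank_sum(target_vals, ctrl_vals,
                           alternative = alternative)
    tibble(
      draw = d,
      statistic = w$statistic,
      p_value = w$p_value,
      method = w$method,
      median_target = median(target_vals),
      median_control = median(ctrl_vals),
      control_ids = list(pool$protein_id[ctrl_idx])
    )
  }) |>
    bind_rows()
  structure(
    list(
      target_n = length(target_vals),
      control_n = length(target_vals),
      statistic = median(draws$statistic),
      p_value = median(draws$p_value),
      medians = c(target = median(target_vals),
                  control = median(draws$median_control)),
      alternative = alternative,
      seed = seed,
      n_draws = n_draws,
      exclude_targets = exclude_targets,
      target_values = target_vals,
      control_values = {
        ctrl1 <- draws$control_ids[[1]]
        pool$mean[match(ctrl1, pool$protein_id)]
      },
      draws = draws
    ),
    class = "disorder_comparison"
  )
}

#' @export
print.disorder_comparison <- function(x, ...) {
  cat("Disorder comparison (Wilcoxon rank-sum, ", x$alternative, ")\n",
      sep = "")
  cat(sprintf("  target n = %d, control n = %d (seed %s, %d draw%s)\n",
              x$target_n, x$control_n, format(x$seed), x$n_draws,
              if (x$n_draws > 1) "s" else ""))
  cat(sprintf("  median disorder: target %.3f, control %.3f\n",
              x$medians[["target"]], x$medians[["control"]]))
  cat(sprintf("  W = %g, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' @export
tidy.disorder_comparison <- function(x, ...) {
  x$draws |> select(!"control_ids")
}

#' @export
glance.disorder_comparison <- function(x, ...) {
  tibble(
    target_n = x$target_n,
    control_n = x$control_n,
    statistic = x$statistic,
    p_value = x$p_value,
    median_target = x$medians[["target"]],
    median_control = x$medians[["control"]],
    alternative = x$alternative,
    n_draws = x$n_draws,
    seed = x$seed
  )
}
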