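#' Harmonize protein identifiers through an alias table
#'
#' Maps candidate and reference identifiers onto canonical gene names
#' before intersection, so the same protein recorded under different
#' synonyms (e.g. `WAGO-9` vs `HRDE-1`) is counted once. Aliases are
#' single-step: an alias that maps to another alias (a chain or cycle), or
#' one alias with two different canonical targets, is an error. Unmapped
#' identifiers pass through unchanged.
#'
#' @param ids Character vector of identifiers.
#' @param alias_map Data frame with columns `alias` and `canonical`, or
#'   `NULL` for the identity mapping.
#' @return Character vector of the same length with aliases replaced.
#' @examples
#' harmonize_ids(c("WAGO-9", "PGL-1"),
#'               data.frame(alias = "WAGO-9", canonical = "HRDE-1"))
#' @export
harmonize_ids <- function(ids, alias_map = NULL) {
  ids <- toupper(as.character(ids))
  if (is.null(alias_map) || nrow(alias_map) == 0L) {
    return(ids)
  }
  if (!all(c("alias", "canonical") %in% names(alias_map))) {
    stop_config("`alias_map` needs columns `alias` and `canonical`.")
  }
  alias <- toupper(alias_map$alias)
  canonical <- toupper(alias_map$canonical)
  dup <- alias[duplicated(alias)]
  conflicting <- unique(dup[vapply(dup, function(a) {
    length(unique(canonical[alias == a])) > 1L
  }, logical(1))])
  if (length(conflicting)) {
    stop_value(sprintf("Conflicting aliases for: %s.",
                       paste(conflicting, collapse = ", ")))
  }
  chained <- canonical[canonical %in% alias &
                         canonical != alias]
  if (length(chained)) {
    stop_value(sprintf(
      "Alias chain/cycle: canonical id(s) %s are themselves aliases.",
      paste(unique(chained), collapse = ", ")
    ))
  }
  idx <- match(ids, alias)
  out <- ids
  out[!is.na(idx)] <- canonical[idx[!is.na(idx)]]
  out
}

#' Score recovery of curated granule reference sets
#'
#' For each curated set (e.g. known P granule, Z granule and Mutator foci
#' proteins), counts how many members appear in the enriched candidate
#' list and reports the recovery fraction.
#'
#' @param candidates Character vector of enriched candidate identifiers.
#' @param references Data frame with columns `protein_id` and `granule`
#'   (one row per known member per set).
#' @param alias_map Optional alias table passed to [harmonize_ids()];
#'   applied to both sides before intersection.
#'
#' @return A tibble of class `"recovery_report"`, one row per granule
#'   sorted by name, with columns `granule`, `n_known`, `n_recovered`,
#'   `fraction`, `recovered_ids`, `missed_ids` (list-columns) and
#'   `empty_set` flag. An empty reference set is kept with `fraction = 0`
#'   and `empty_set = TRUE`, with a warning.
#' @examples
#' refs <- data.frame(protein_id = c("pgl-1", "glh-1", "znfx-1"),
#'                    granule = c("P granule", "P granule", "Z granule"))
#' recovery(c("PGL-1", "ZNFX-1"), refs)
#' @export
recovery <- function(candidates, references, alias_map = NULL) {
  if (!is.data.frame(references) ||
      !all(c("protein_id", "granule") %in% names(references))) {
    stop_config("`references` needs columns `protein_id` and `granule`.")
  }
  if (nrow(references) == 0L) {
    stop_config("`references` must contain at least one set member.")
  }
  granules <- sort(unique(as.character(references$granule)))
  keep <- !is.na(references$protein_id) & nzchar(references$protein_id)
  if (!all(keep)) {
    warn("Reference rows with blank protein ids dropped.")
    references <- references[keep, , drop = FALSE]
  }
  cand <- unique(harmonize_ids(candidates, alias_map))
  refs <- tibble(
    granule = as.character(references$granule),
    protein_id = harmonize_ids(references$protein_id, alias_map)
  ) |>
    distinct()
  rows <- purrr::map(granules, function(g) {
    members <- sort(refs$protein_id[refs$granule == g])
    hit <- members %in% cand
    tibble(
      granule = g,
      n_known = length(members),
      n_recovered = sum(hit),
      fraction = if (length(members)) sum(hit) / length(members) else 0,
      recovered_ids = list(members[hit]),
      missed_ids = list(members[!hit]),
      empty_set = length(members) == 0L
    )
  })
  out <- bind_rows(rows)
  if (any(out$empty_set)) {
    warn("Empty reference set(s); their recovery fraction is reported as 0.")
  }
  structure(out, class = c("recovery_report", class(out)))
}

#' @export
glance.recovery_report <- function(x, ...) {
  tibble(
    n_sets = nrow(x),
    n_known_total = sum(x$n_known),
    n_recovered_total = sum(x$n_recovered),
    overall_fraction = ifelse(sum(x$n_known) > 0,
                              sum(x$n_recovered) / sum(x$n_known), 0)
  )
}

#' @export
tidy.recovery_report <- function(x, ...) {
  as_tibble(x) |>
    select(!c("recovered_ids", "missed_ids"))
}
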