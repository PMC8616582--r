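#' Configuration for the end-to-end pipeline
#'
#' Collects every input of [run_pipeline()]. Each data input may be given
#' either as an in-memory data frame or as a path to the corresponding
#' plain-text file (paths are checked up front; a missing path is a
#' configuration error).
#'
#' @param counts_a,samples_a Counts table and sample sheet for bait A.
#' @param counts_b,samples_b Counts table and sample sheet for bait B.
#' @param references Curated reference sets (`protein_id`, `granule`), or
#'   `NULL` to skip recovery scoring.
#' @param disorder Per-protein disorder summary (`protein_id`, `mean`) or
#'   long per-residue scores (`protein_id`, `position`, `score`), or
#'   `NULL` to skip the disorder stage.
#' @param disorder_targets Protein ids whose disorder is compared to a
#'   random control; `NULL` (default) uses the proteins enriched by both
#'   baits.
#' @param roi ROI measurement table, or `NULL` to skip.
#' @param alias Optional alias table (`alias`, `canonical`).
#' @param enrichment An [enrichment_config()].
#' @param seed Integer seed driving the random-control draw.
#' @param n_draws,alternative,exclude_targets Passed to
#'   [compare_to_random()].
#' @param roi_mode Passed to [rachis_edge_ratio()].
#'
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(counts_a, samples_a, counts_b, samples_b,
                            references = NULL,
                            disorder = NULL,
                            disorder_targets = NULL,
                            roi = NULL,
                            alias = NULL,
                            enrichment = enrichment_config(),
                            seed = 1L,
                            n_draws = 1,
                            alternative = "two-sided",
                            exclude_targets = TRUE,
                            roi_mode = "symmetric") {
  inputs <- list(counts_a = counts_a, samples_a = samples_a,
                 counts_b = counts_b, samples_b = samples_b,
                 references = references, disorder = disorder,
                 roi = roi, alias = alias)
  for (nm in names(inputs)) {
    x <- inputs[[nm]]
    if (is.null(x) || is.data.frame(x)) next
    if (is.character(x) && length(x) == 1L) {
      if (!file.exists(x)) {
        stop_config(sprintf("Input `%s` path does not exist: %s", nm, x))
      }
    } else {
      stop_config(sprintf("Input `%s` must be a data frame or a path.", nm))
    }
  }
  if (!inherits(enrichment, "enrichment_config")) {
    stop_config("`enrichment` must come from enrichment_config().")
  }
  check_scalar_number(seed, "seed")
  structure(
    c(inputs,
      list(disorder_targets = disorder_targets, enrichment = enrichment,
           seed = as.integer(seed), n_draws = n_draws,
           alternative = alternative, exclude_targets = exclude_targets,
           roi_mode = roi_mode)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds the file-path fields of [pipeline_config()] plus
#' optional `enrichment:` (fields of [enrichment_config()]) and scalar
#' settings; a config read from YAML round-trips unchanged.
#'
#' @param path YAML file.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop_config(sprintf("Config file not found: %s", path))
  }
  y <- yaml::read_yaml(path)
  enr <- do.call(enrichment_config, y$enrichment %||% list())
  y$enrichment <- NULL
  base <- dirname(path)
  path_fields <- c("counts_a", "samples_a", "counts_b", "samples_b",
                   "references", "disorder", "roi", "alias")
  for (f in intersect(path_fields, names(y))) {
    if (!file.exists(y[[f]]) && file.exists(file.path(base, y[[f]]))) {
      y[[f]] <- file.path(base, y[[f]])
    }
  }
  do.call(pipeline_config, c(y, list(enrichment = enr)))
}

resolve_input <- function(x, reader) {
  if (is.null(x) || is.data.frame(x)) x else reader(x)
}

run_stage <- function(stage, code) {
  tryCatch(
    force(code),
    error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)),
            class = "proxitome_stage_error", parent = e)
    }
  )
}

#' Run the full proximity-labeling analysis pipeline
#'
#' Executes every stage in order — per-bait enrichment calling, dual-bait
#' intersection, reference-set recovery, disorder comparison against a
#' seeded random control, and ROI ratio summarisation — and collects the
#' headline numbers into one machine-readable summary. Any stage failure
#' aborts with a stage-labelled error; outputs written before the failure
#' are retained.
#'
#' @param config A [pipeline_config()] (or path to its YAML file).
#' @param out_dir Optional directory; when given, per-stage tables
#'   (enrichment TSVs, candidate lists, recovery and Venn JSON/TSV, ROI
#'   ratios) and `summary.json` are written there as they are produced.
#'
#' @return A list of class `"pipeline_report"`: `enrichment_a`,
#'   `enrichment_b`, `venn`, `recovery`, `disorder`, `roi`, and `summary`
#'   (the list serialised to `summary.json`, including the config hash and
#'   package version).
#' @examples
#' bundle <- simulate_bundle(simulation_spec(seed = 7, n_proteins = 300),
#'                           n_enriched_a = 30, n_enriched_b = 25,
#'                           n_shared = 15)
#' cfg <- pipeline_config(bundle$bait_a$counts, bundle$bait_a$samples,
#'                        bundle$bait_b$counts, bundle$bait_b$samples,
#'                        references = bundle$references,
#'                        disorder = bundle$disorder$summaries,
#'                        roi = bundle$roi, seed = 7)
#' report <- run_pipeline(cfg)
#' report$summary$both
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    stop_config("`config` must come from pipeline_config().")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(writer, x, file) {
    if (!is.null(out_dir)) writer(x, file.path(out_dir, file))
  }

  alias <- resolve_input(config$alias, read_alias_map)

  enr_a <- run_stage("enrichment-a", {
    call_enrichment(resolve_input(config$counts_a, read_counts),
                    resolve_input(config$samples_a, read_sample_sheet),
                    config$enrichment)
  })
  emit(write_enrichment, enr_a, "enrichment_a.tsv")
  enr_b <- run_stage("enrichment-b", {
    call_enrichment(resolve_input(config$counts_b, read_counts),
                    resolve_input(config$samples_b, read_sample_sheet),
                    config$enrichment)
  })
  emit(write_enrichment, enr_b, "enrichment_b.tsv")

  ids_a <- enriched_ids(enr_a)
  ids_b <- enriched_ids(enr_b)
  venn <- run_stage("venn", intersect_enrichment(ids_a, ids_b))
  if (!is.null(out_dir)) {
    writeLines(ids_a, file.path(out_dir, "candidates_a.txt"))
    writeLines(ids_b, file.path(out_dir, "candidates_b.txt"))
    writeLines(sort(intersect(ids_a, ids_b)),
               file.path(out_dir, "candidates_both.txt"))
    write_json_file(as.list(venn), file.path(out_dir, "venn.json"))
  }

  rec <- NULL
  references <- resolve_input(config$references, read_reference_sets)
  if (!is.null(references)) {
    rec <- run_stage("recovery", {
      recovery(union(ids_a, ids_b), references, alias_map = alias)
    })
    emit(function(x, f) readr::write_tsv(tidy(x), f), rec, "recovery.tsv")
  }

  dis <- NULL
  disorder_in <- resolve_input(config$disorder, function(p) {
    x <- readr::read_delim(p, delim = delim_for(p), show_col_types = FALSE,
                           progress = FALSE)
    x
  })
  if (!is.null(disorder_in)) {
    dis <- run_stage("disorder", {
      summaries <- if (all(c("position", "score") %in% names(disorder_in))) {
        summarize_disorder(disorder_in)
      } else {
        disorder_in
      }
      targets <- config$disorder_targets %||% intersect(ids_a, ids_b)
      targets <- harmonize_ids(targets, alias)
      summaries$protein_id <- harmonize_ids(summaries$protein_id, alias)
      compare_to_random(summaries, targets, seed = config$seed,
                        n_draws = config$n_draws,
                        alternative = config$alternative,
                        exclude_targets = config$exclude_targets)
    })
    emit(function(x, f) write_json_file(as.list(glance(x)), f),
         dis, "disorder.json")
  }

  roi_sum <- NULL
  roi_in <- resolve_input(config$roi, read_roi_measurements)
  if (!is.null(roi_in)) {
    roi_sum <- run_stage("roi", {
      ratio_summary(rachis_edge_ratio(roi_in, mode = config$roi_mode))
    })
    emit(function(x, f) readr::write_tsv(glance(x), f),
         roi_sum, "roi_groups.tsv")
  }

  cfg_for_hash <- config
  summary <- list(
    package = "proxitome",
    version = as.character(utils::packageVersion("proxitome")),
    seed = config$seed,
    config_hash = rlang::hash(cfg_for_hash),
    enriched_a = length(ids_a),
    enriched_b = length(ids_b),
    only_a = venn$only_a,
    only_b = venn$only_b,
    both = venn$both,
    union = venn$union,
    recovery = if (!is.null(rec)) {
      purrr::map(seq_len(nrow(rec)), function(i) {
        list(granule = rec$granule[i], n_known = rec$n_known[i],
             n_recovered = rec$n_recovered[i], fraction = rec$fraction[i])
      })
    },
    disorder_p = if (!is.null(dis)) dis$p_value,
    disorder_medians = if (!is.null(dis)) as.list(dis$medians),
    roi = if (!is.null(roi_sum)) {
      list(groups = purrr::map(seq_len(nrow(roi_sum$groups)), function(i) {
        list(genotype = roi_sum$groups$genotype[i],
             n = roi_sum$groups$n[i],
             mean_ratio = roi_sum$groups$mean[i])
      }),
      tests = purrr::map(seq_len(nrow(roi_sum$tests)), function(i) {
        list(group1 = roi_sum$tests$group1[i],
             group2 = roi_sum$tests$group2[i],
             p_value = roi_sum$tests$p_value[i])
      }))
    }
  )
  if (!is.null(out_dir)) {
    write_json_file(summary, file.path(out_dir, "summary.json"))
  }
  structure(
    list(enrichment_a = enr_a, enrichment_b = enr_b, venn = venn,
         recovery = rec, disorder = dis, roi = roi_sum, summary = summary),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("Proximity-labeling pipeline report\n")
  cat(sprintf("  enriched: bait A %d, bait B %d; both %d, union %d\n",
              s$enriched_a, s$enriched_b, s$both, s$union))
  if (!is.null(s$recovery)) {
    for (r in s$recovery) {
      cat(sprintf("  recovery %s: %d/%d (%.0f%%)\n", r$granule,
                  r$n_recovered, r$n_known, 100 * r$fraction))
    }
  }
  if (!is.null(s$disorder_p)) {
    cat(sprintf("  disorder p = %.3g\n", s$disorder_p))
  }
  invisible(x)
}
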