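#' Specification for the synthetic study generator
#'
#' Collects every parameter of the seeded generators that emulate the
#' proximity-labeling study design: replicate spectral-count matrices with
#' a contaminant background and a planted enriched subset, per-residue
#' disorder scores with a mean shift for a target class, curated reference
#' sets with a configured overlap, and ROI intensity records with additive
#' background. All generators are pure functions of this spec: the same
#' seed always yields the same data, and each generator draws from its own
#' sub-stream derived from `seed`.
#'
#' Defaults describe the emulated study conditions: 2,000 detected
#' proteins, 3 replicates per group, a negative-binomial contaminant
#' background (mean 10 spectral counts, size 5) with 10% detection
#' dropout at background abundance (decaying with abundance), a 16-fold
#' planted enrichment — one doubling above the fold-change calling
#' threshold, mirroring the strong labeling of bona fide granule
#' components — a +0.2 disorder shift for the target class, and reference
#' sets overlapping the enriched truth as 18/20 (P granule), 2/2
#' (Z granule) and 0/11 (Mutator foci).
#'
#' @param seed Integer master seed.
#' @param n_proteins Number of proteins in the simulated proteome.
#' @param n_enriched Number of truly bait-proximal (enriched) proteins.
#' @param n_replicates Replicates per group (default 3).
#' @param background_mean Mean spectral count of the contaminant
#'   background (negative binomial), > 0.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed), > 0.
#' @param effect_fold Fold increase of the bait-group mean for enriched
#'   proteins, > 1.
#' @param detection_zero_prob Probability that a background-level
#'   measurement drops to zero (detection failure), in `[0, 1)`; the
#'   dropout probability decays exponentially as the expected abundance
#'   rises above `background_mean`.
#' @param disorder_shift Added to the disorder propensity mean of target
#'   proteins (clipped into (0, 1) with a warning).
#' @param reference_overlap Named list; each element `c(n_known,
#'   n_in_enriched)` describes a curated set of `n_known` proteins of
#'   which `n_in_enriched` lie inside the enriched truth set.
#'
#' @return A list of class `"simulation_spec"`.
#' @examples
#' simulation_spec(seed = 42)
#' @export
simulation_spec <- function(seed,
                            n_proteins = 2000,
                            n_enriched = 50,
                            n_replicates = 3,
                            background_mean = 10,
                            dispersion = 5,
                            effect_fold = 16,
                            detection_zero_prob = 0.1,
                            disorder_shift = 0.2,
                            reference_overlap = list(
                              "P granule" = c(20, 18),
                              "Z granule" = c(2, 2),
                              "Mutator foci" = c(11, 0)
                            )) {
  check_scalar_number(seed, "seed")
  check_scalar_number(n_proteins, "n_proteins", min = 1)
  check_scalar_number(n_enriched, "n_enriched", min = 0, max = n_proteins)
  check_scalar_number(n_replicates, "n_replicates", min = 2)
  check_scalar_number(background_mean, "background_mean", min = 0,
                      strict_min = TRUE)
  check_scalar_number(dispersion, "dispersion", min = 0, strict_min = TRUE)
  check_scalar_number(effect_fold, "effect_fold", min = 1)
  check_scalar_number(detection_zero_prob, "detection_zero_prob",
                      min = 0, max = 1 - 1e-12)
  structure(
    list(
      seed = as.integer(seed),
      n_proteins = as.integer(n_proteins),
      n_enriched = as.integer(n_enriched),
      n_replicates = as.integer(n_replicates),
      background_mean = background_mean,
      dispersion = dispersion,
      effect_fold = effect_fold,
      detection_zero_prob = detection_zero_prob,
      disorder_shift = disorder_shift,
      reference_overlap = reference_overlap
    ),
    class = "simulation_spec"
  )
}

protein_ids <- function(n) {
  sprintf("P%05d", seq_len(n))
}

# Zero-inflated negative binomial draws. Detection dropout is
# abundance-dependent: the configured zero probability applies at the
# contaminant background level and decays exponentially with the mean
# above it, so strongly labeled proteins are essentially always detected.
rzinb <- function(n, mu, size, zero_prob, ref_mean) {
  x <- rnbinom(n, mu = mu, size = size)
  if (zero_prob > 0) {
    p0 <- zero_prob * pmin(1, exp(-(mu - ref_mean) / ref_mean))
    x[rbinom(n, 1L, p0) == 1L] <- 0L
  }
  as.double(x)
}

#' Simulate a replicate spectral-count matrix with planted enrichment
#'
#' Control counts are drawn from a zero-inflated negative binomial
#' (contaminant background); bait counts of the planted enriched proteins
#' are drawn at `effect_fold` times the background mean, null proteins
#' from the background in both groups.
#'
#' @param spec A [simulation_spec()].
#' @param enriched_ids Optional character vector naming the planted
#'   enriched proteins; by default `spec$n_enriched` proteins are sampled.
#' @param label Sample-name prefix for the bait columns (also salts the
#'   RNG sub-stream, so two baits simulated from one spec differ).
#'
#' @return A list: `counts` (wide tibble, `protein_id` + sample columns),
#'   `samples` (sample sheet), `truth` (tibble `protein_id`,
#'   `enriched`).
#' @examples
#' sim <- simulate_counts(simulation_spec(seed = 1, n_proteins = 100,
#'                                        n_enriched = 5))
#' head(sim$counts)
#' @export
simulate_counts <- function(spec, enriched_ids = NULL, label = "bait") {
  stopifnot(inherits(spec, "simulation_spec"))
  ids <- protein_ids(spec$n_proteins)
  with_seed_local(derive_seed(spec$seed, paste0("counts-", label)), {
    if (is.null(enriched_ids)) {
      enriched_ids <- sort(sample(ids, spec$n_enriched))
    }
    if (!all(enriched_ids %in% ids)) {
      stop_value("`enriched_ids` must be simulated protein ids.")
    }
    is_enr <- ids %in% enriched_ids
    n <- spec$n_proteins
    reps <- spec$n_replicates
    bait_mu <- ifelse(is_enr, spec$effect_fold * spec$background_mean,
                      spec$background_mean)
    bait <- vapply(seq_len(reps), function(r) {
      rzinb(n, bait_mu, spec$dispersion, spec$detection_zero_prob,
            spec$background_mean)
    }, numeric(n))
    ctrl <- vapply(seq_len(reps), function(r) {
      rzinb(n, spec$background_mean, spec$dispersion,
            spec$detection_zero_prob, spec$background_mean)
    }, numeric(n))
    bait_names <- paste0(label, "_", seq_len(reps))
    ctrl_names <- paste0("control_", seq_len(reps))
    counts <- bind_cols(
      tibble(protein_id = ids),
      as_tibble(`colnames<-`(bait, bait_names)),
      as_tibble(`colnames<-`(ctrl, ctrl_names))
    )
    list(
      counts = counts,
      samples = tibble(
        sample_id = c(bait_names, ctrl_names),
        group = rep(c("bait", "control"), each = reps),
        replicate = rep(seq_len(reps), 2)
      ),
      truth = tibble(protein_id = ids, enriched = is_enr)
    )
  })
}

#' Simulate per-residue disorder scores with a shifted target class
#'
#' Protein lengths are log-normal (median 400 residues, sdlog 0.5,
#' minimum 30). Each protein gets a disorder propensity drawn from a Beta
#' distribution (mean 0.35, concentration 6); target proteins' propensity
#' mean is shifted by `spec$disorder_shift`. Per-residue scores are then
#' Beta draws centred on the propensity (concentration 3), so scores vary
#' along the chain while the per-protein mean tracks the propensity.
#'
#' @param spec A [simulation_spec()].
#' @param target_ids Character vector of target proteins (default: the
#'   first `spec$n_enriched` simulated ids).
#'
#' @return A list: `scores` (long tibble `protein_id`, `position`,
#'   `score`), `summaries` (per-protein `length`, `total`, `mean`),
#'   `target_ids`.
#' @export
simulate_disorder <- function(spec, target_ids = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  ids <- protein_ids(spec$n_proteins)
  if (is.null(target_ids)) {
    target_ids <- ids[seq_len(spec$n_enriched)]
  }
  if (!all(target_ids %in% ids)) {
    stop_value("`target_ids` must be simulated protein ids.")
  }
  base_mean <- 0.35
  propensity_conc <- 6
  residue_conc <- 3
  with_seed_local(derive_seed(spec$seed, "disorder"), {
    lens <- pmax(30L, as.integer(round(rlnorm(spec$n_proteins,
                                              meanlog = log(400),
                                              sdlog = 0.5))))
    mu <- rep(base_mean, spec$n_proteins)
    mu[ids %in% target_ids] <- base_mean + spec$disorder_shift
    if (any(mu <= 0 | mu >= 1)) {
      warn("disorder_shift pushes the propensity mean outside (0, 1); clipped.")
      mu <- pmin(pmax(mu, 0.02), 0.98)
    }
    theta <- rbeta(spec$n_proteins, mu * propensity_conc,
                   (1 - mu) * propensity_conc)
    theta <- pmin(pmax(theta, 1e-3), 1 - 1e-3)
    pid <- rep(ids, lens)
    score <- rbeta(sum(lens), rep(theta, lens) * residue_conc,
                   rep(1 - theta, lens) * residue_conc)
    scores <- tibble(
      protein_id = pid,
      position = sequence(lens),
      score = score
    )
    totals <- rowsum(score, pid)
    ord <- order(rownames(totals))
    summaries <- tibble(
      protein_id = rownames(totals)[ord],
      length = lens[match(rownames(totals)[ord], ids)],
      total = unname(totals[ord, 1])
    ) |>
      mutate(mean = .data$total / .data$length)
    list(scores = scores, summaries = summaries,
         target_ids = sort(target_ids))
  })
}

#' Simulate curated reference sets with a configured overlap
#'
#' Builds one curated set per entry of `spec$reference_overlap`: `n_known`
#' members, of which `n_in_enriched` are drawn from the enriched truth set
#' and the rest from the non-enriched proteins, so downstream recovery
#' reproduces the configured fractions structurally.
#'
#' @param spec A [simulation_spec()].
#' @param truth Truth tibble from [simulate_counts()] (`protein_id`,
#'   `enriched`), or a list of enriched ids plus a full id universe via
#'   `enriched_ids`/`all_ids`.
#'
#' @return A tibble with columns `protein_id`, `granule`.
#' @export
simulate_reference <- function(spec, truth) {
  stopifnot(inherits(spec, "simulation_spec"))
  enr <- truth$protein_id[truth$enriched]
  nul <- truth$protein_id[!truth$enriched]
  with_seed_local(derive_seed(spec$seed, "reference"), {
    sets <- purrr::imap(spec$reference_overlap, function(ov, granule) {
      n_known <- ov[[1]]
      n_in <- ov[[2]]
      if (n_in > length(enr) || (n_known - n_in) > length(nul) ||
          n_in > n_known) {
        stop_value(sprintf("Overlap (%d, %d) for '%s' exceeds set sizes.",
                           n_known, n_in, granule))
      }
      tibble(
        protein_id = c(sample(enr, n_in), sample(nul, n_known - n_in)),
        granule = granule
      )
    })
    bind_rows(sets) |> arrange(.data$granule, .data$protein_id)
  })
}

#' Simulate ROI mean-intensity records
#'
#' Generates per-animal rachis/edge/background mean gray values such that
#' the symmetric background-corrected rachis/edge ratio equals the planted
#' per-genotype ratio plus additive Gaussian measurement noise.
#'
#' @param spec A [simulation_spec()].
#' @param genotype_ratios Named vector of planted true ratios.
#' @param n_animals Animals per genotype (default 4).
#' @param background True background mean gray value.
#' @param edge_mean Mean edge intensity above background.
#' @param noise_sd Additive intensity noise (gray values); 0 recovers the
#'   planted ratio exactly.
#'
#' @return A tibble with columns `animal_id`, `genotype`, `rachis`,
#'   `edge1`, `edge2`, `background`.
#' @export
simulate_roi <- function(spec,
                         genotype_ratios = c("wild-type" = 0.30,
                                             "eggd-1" = 0.70,
                                             "eggd-2" = 0.35,
                                             "eggd-1; eggd-2" = 0.90),
                         n_animals = 4,
                         background = 10,
                         edge_mean = 100,
                         noise_sd = 2) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed_local(derive_seed(spec$seed, "roi"), {
    rows <- purrr::imap(genotype_ratios, function(ratio, genotype) {
      edge1 <- background + edge_mean + rnorm(n_animals, sd = noise_sd)
      edge2 <- background + edge_mean + rnorm(n_animals, sd = noise_sd)
      rachis <- background +
        ratio * (edge1 + edge2 - 2 * background) / 2 +
        rnorm(n_animals, sd = noise_sd)
      tibble(
        animal_id = paste0(gsub("[^a-z0-9]+", "-", genotype), "_",
                           seq_len(n_animals)),
        genotype = genotype,
        rachis = pmax(rachis, 0),
        edge1 = pmax(edge1, 0),
        edge2 = pmax(edge2, 0),
        background = background
      )
    })
    bind_rows(rows)
  })
}

#' Simulate the full dual-bait study bundle
#'
#' Composes the generators into the complete input bundle the pipeline
#' consumes: two bait count matrices against a shared contaminant
#' background with overlapping planted truth sets (defaults at the study
#' scale: 155 and 127 enriched with 78 shared), disorder scores whose
#' target class is the shared truth set, curated reference sets, and ROI
#' records.
#'
#' @param spec A [simulation_spec()].
#' @param n_enriched_a,n_enriched_b Planted enriched proteins per bait.
#' @param n_shared Planted overlap between the two baits' truth sets.
#'
#' @return A list with elements `bait_a`, `bait_b` (each as
#'   [simulate_counts()] output), `truth_a`, `truth_b`, `shared_truth`,
#'   `references`, `disorder`, `roi`, `spec`.
#' @examples
#' bundle <- simulate_bundle(simulation_spec(seed = 5, n_proteins = 300),
#'                           n_enriched_a = 30, n_enriched_b = 25,
#'                           n_shared = 15)
#' @export
simulate_bundle <- function(spec, n_enriched_a = 155, n_enriched_b = 127,
                            n_shared = 78) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (n_shared > min(n_enriched_a, n_enriched_b)) {
    stop_value("`n_shared` cannot exceed either bait's enriched count.")
  }
  n_union <- n_enriched_a + n_enriched_b - n_shared
  if (n_union > spec$n_proteins) {
    stop_value("Combined truth set larger than the proteome.")
  }
  ids <- protein_ids(spec$n_proteins)
  sets <- with_seed_local(derive_seed(spec$seed, "bundle-truth"), {
    pool <- sample(ids, n_union)
    a_only <- pool[seq_len(n_enriched_a - n_shared)]
    shared <- pool[n_enriched_a - n_shared + seq_len(n_shared)]
    b_only <- pool[n_enriched_a + seq_len(n_enriched_b - n_shared)]
    list(a = sort(c(a_only, shared)), b = sort(c(b_only, shared)),
         shared = sort(shared))
  })
  bait_a <- simulate_counts(spec, enriched_ids = sets$a, label = "baitA")
  bait_b <- simulate_counts(spec, enriched_ids = sets$b, label = "baitB")
  truth_union <- tibble(
    protein_id = ids,
    enriched = ids %in% union(sets$a, sets$b)
  )
  disorder <- simulate_disorder(spec, target_ids = sets$shared)
  references <- simulate_reference(spec, truth_union)
  roi <- simulate_roi(spec)
  list(
    bait_a = bait_a,
    bait_b = bait_b,
    truth_a = bait_a$truth,
    truth_b = bait_b$truth,
    shared_truth = sets$shared,
    references = references,
    disorder = disorder,
    roi = roi,
    spec = spec
  )
}
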