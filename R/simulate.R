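#' Configure a synthetic replicate IP-MS experiment
#'
#' Builds a validated configuration for [simulate_ipms()]. The generator
#' emulates a label-free affinity-purification experiment: a high-abundance
#' bait protein immunoprecipitated in every run, prey proteins whose peptide
#' ions carry multiplicative log-normal variation, per-run global scale
#' factors (IP efficiency / loading), and missing-completely-at-random
#' peptide observations. A configurable subset of prey proteins is "spiked"
#' with a known true fold change between the test and reference groups, so
#' the full quantification and testing pipeline can be checked against a
#' known answer.
#'
#' Peptide intensities are generated on the natural-log scale as
#' `base_log_mean + protein deviation + peptide deviation + run noise`
#' (plus the log run scale factor and, for spiked proteins in test-group
#' runs, the log true fold change). The protein and peptide deviations have
#' mean zero, so with unit scale factors the expected log intensity of a
#' prey peptide ion equals `base_log_mean`.
#'
#' @param n_proteins Number of prey proteins (the bait is generated in
#'   addition to these).
#' @param peptides_per_protein Length-2 integer vector `c(min, max)`;
#'   each protein's peptide count is drawn uniformly from this range.
#' @param replicates_per_group Runs per group; at least 2 (a t-test needs
#'   two replicates). Default 3, the usual contemporaneous-IP design.
#' @param group_labels Named character vector
#'   `c(reference = ..., test = ...)`.
#' @param bait_accession Accession of the bait protein.
#' @param bait_abundance_multiplier Fold abundance of the bait above the
#'   median prey protein. Baits dominate IP eluates, hence the large default.
#' @param base_log_mean,base_log_sd Mean of prey log peptide intensity and
#'   the standard deviation of the per-run replicate noise, natural-log scale.
#' @param protein_log_sd,peptide_log_sd Standard deviations of the
#'   protein-level abundance deviation and the per-peptide ionization
#'   efficiency deviation (constant across runs), natural-log scale.
#' @param spiked_proteins Named numeric vector mapping prey accessions
#'   (e.g. `"PROT0003"`) to true fold changes (test / reference, > 0).
#' @param missingness_rate Probability that a prey peptide ion is
#'   unobserved in a given run (independent per ion per run; the bait is
#'   never subject to missingness).
#' @param run_scale_factors Either a positive numeric vector recycled to
#'   one value per run, or the string `"random"` to draw
#'   `exp(rnorm(0, run_scale_log_sd))` per run.
#' @param run_scale_log_sd Log-scale sd used when `run_scale_factors` is
#'   `"random"`.
#' @param shared_peptide_fraction Fraction of prey peptides additionally
#'   assigned to a second protein, to exercise the unique-peptide rollup
#'   rule. Default 0.
#' @param seed Default seed used by [simulate_ipms()] when no explicit
#'   seed is passed.
#'
#' @return A list of class `ipms_sim_config`.
#' @seealso [simulate_ipms()], [simulate_null_ipms()]
#' @export
#' @examples
#' cfg <- sim_config(n_proteins = 20, spiked_proteins = c(PROT0001 = 2))
#' sim <- simulate_ipms(cfg, seed = 1)
#' dplyr::count(sim$peptides, run_id)
sim_config <- function(n_proteins = 150,
                       peptides_per_protein = c(2L, 20L),
                       replicates_per_group = 3L,
                       group_labels = c(reference = "WT", test = "KO"),
                       bait_accession = "BAIT",
                       bait_abundance_multiplier = 50,
                       base_log_mean = log(1e6),
                       base_log_sd = 0.25,
                       protein_log_sd = 1,
                       peptide_log_sd = 0.5,
                       spiked_proteins = numeric(),
                       missingness_rate = 0,
                       run_scale_factors = 1,
                       run_scale_log_sd = 0.5,
                       shared_peptide_fraction = 0,
                       seed = 1L) {
  check_count <- function(x, name, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != as.integer(x)) {
      abort(sprintf("`%s` must be a single integer >= %d", name, min),
            class = "ipmsdiff_config_error")
    }
  }
  check_count(n_proteins, "n_proteins")
  check_count(replicates_per_group, "replicates_per_group", min = 2)
  if (!is.numeric(peptides_per_protein) || length(peptides_per_protein) != 2 ||
      any(peptides_per_protein < 1) ||
      peptides_per_protein[1] > peptides_per_protein[2]) {
    abort("`peptides_per_protein` must be c(min, max) with 1 <= min <= max",
          class = "ipmsdiff_config_error")
  }
  if (length(group_labels) != 2 ||
      !all(c("reference", "test") %in% names(group_labels)) ||
      anyDuplicated(group_labels)) {
    abort("`group_labels` must be two distinct labels named 'reference' and 'test'",
          class = "ipmsdiff_config_error")
  }
  if (!is.character(bait_accession) || length(bait_accession) != 1 ||
      !nzchar(bait_accession)) {
    abort("`bait_accession` must be a non-empty string",
          class = "ipmsdiff_config_error")
  }
  for (nm in c("bait_abundance_multiplier", "base_log_sd", "protein_log_sd",
               "peptide_log_sd", "run_scale_log_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive number", nm),
            class = "ipmsdiff_config_error")
    }
  }
  if (!is.numeric(base_log_mean) || length(base_log_mean) != 1 || is.na(base_log_mean)) {
    abort("`base_log_mean` must be a single number", class = "ipmsdiff_config_error")
  }
  if (length(spiked_proteins) > 0) {
    if (!is.numeric(spiked_proteins) || is.null(names(spiked_proteins)) ||
        any(!nzchar(names(spiked_proteins))) || any(spiked_proteins <= 0)) {
      abort("`spiked_proteins` must be a named numeric vector of positive fold changes",
            class = "ipmsdiff_config_error")
    }
    if (bait_accession %in% names(spiked_proteins)) {
      abort("`spiked_proteins` must not contain the bait accession",
            class = "ipmsdiff_config_error")
    }
  }
  if (!is.numeric(missingness_rate) || length(missingness_rate) != 1 ||
      is.na(missingness_rate) || missingness_rate < 0 || missingness_rate > 1) {
    abort("`missingness_rate` must be in [0, 1]", class = "ipmsdiff_config_error")
  }
  if (!(identical(run_scale_factors, "random") ||
        (is.numeric(run_scale_factors) && all(run_scale_factors > 0)))) {
    abort("`run_scale_factors` must be positive numbers or \"random\"",
          class = "ipmsdiff_config_error")
  }
  if (!is.numeric(shared_peptide_fraction) || shared_peptide_fraction < 0 ||
      shared_peptide_fraction > 0.5) {
    abort("`shared_peptide_fraction` must be in [0, 0.5]",
          class = "ipmsdiff_config_error")
  }
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      peptides_per_protein = as.integer(peptides_per_protein),
      replicates_per_group = as.integer(replicates_per_group),
      group_labels = group_labels,
      bait_accession = bait_accession,
      bait_abundance_multiplier = bait_abundance_multiplier,
      base_log_mean = base_log_mean,
      base_log_sd = base_log_sd,
      protein_log_sd = protein_log_sd,
      peptide_log_sd = peptide_log_sd,
      spiked_proteins = spiked_proteins,
      missingness_rate = missingness_rate,
      run_scale_factors = run_scale_factors,
      run_scale_log_sd = run_scale_log_sd,
      shared_peptide_fraction = shared_peptide_fraction,
      seed = as.integer(seed)
    ),
    class = "ipms_sim_config"
  )
}

random_peptide_sequences <- function(n, min_len = 7, max_len = 20) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lens <- sample(min_len:max_len, n, replace = TRUE)
  seqs <- vapply(lens, function(l) paste(sample(aa, l, replace = TRUE), collapse = ""),
                 character(1))
  # regenerate collisions until sequences are unique (vanishingly rare)
  while (anyDuplicated(seqs)) {
    dup <- duplicated(seqs)
    seqs[dup] <- random_peptide_sequences(sum(dup), min_len, max_len)
  }
  seqs
}

#' Generate a synthetic IP-MS peptide table with known ground truth
#'
#' Draws one experiment from the model described in [sim_config()] and
#' returns both the peptide-ion table (the same shape
#' [read_peptide_table()] produces) and the ground truth behind it.
#' Identical `(config, seed)` pairs yield identical tables; all randomness
#' is local to the call (the global RNG state is untouched).
#'
#' @param config An `ipms_sim_config` from [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#'
#' @return A list with elements
#'   \describe{
#'     \item{peptides}{Tibble of peptide-ion observations with columns
#'       `run_id`, `group`, `accession`, `description`, `peptide`,
#'       `charge`, `intensity`.}
#'     \item{truth}{Tibble with one row per generated protein: `accession`,
#'       `true_fold_change` (test/reference; 1 for non-spiked proteins and
#'       the bait) and `true_mean_reference`, the protein's true
#'       bait-normalized abundance in the reference group.}
#'   }
#' @export
simulate_ipms <- function(config, seed = config$seed) {
  if (!inherits(config, "ipms_sim_config")) {
    abort("`config` must come from sim_config()", class = "ipmsdiff_config_error")
  }
  withr::with_seed(seed, simulate_ipms_impl(config))
}

simulate_ipms_impl <- function(config) {
  n_rep <- config$replicates_per_group
  groups <- config$group_labels
  runs <- tibble(
    run_id = c(paste0(groups[["reference"]], "_", seq_len(n_rep)),
               paste0(groups[["test"]], "_", seq_len(n_rep))),
    group = rep(c(groups[["reference"]], groups[["test"]]), each = n_rep)
  )
  n_runs <- nrow(runs)
  if (identical(config$run_scale_factors, "random")) {
    runs$scale <- exp(rnorm(n_runs, 0, config$run_scale_log_sd))
  } else {
    runs$scale <- rep_len(config$run_scale_factors, n_runs)
  }

  prey_acc <- sprintf("PROT%04d", seq_len(config$n_proteins))
  unknown_spikes <- setdiff(names(config$spiked_proteins), prey_acc)
  if (length(unknown_spikes) > 0) {
    abort(sprintf("`spiked_proteins` names not among generated accessions: %s",
                  paste(unknown_spikes, collapse = ", ")),
          class = "ipmsdiff_config_error")
  }

  proteins <- tibble(
    accession = c(prey_acc, config$bait_accession),
    is_bait = c(rep(FALSE, config$n_proteins), TRUE),
    base_log = c(config$base_log_mean + rnorm(config$n_proteins, 0, config$protein_log_sd),
                 config$base_log_mean + log(config$bait_abundance_multiplier))
  )
  proteins$description <- if_else(proteins$is_bait,
                                  "Synthetic bait protein",
                                  paste("Synthetic prey protein", proteins$accession))
  fold <- setNames(rep(1, nrow(proteins)), proteins$accession)
  fold[names(config$spiked_proteins)] <- config$spiked_proteins

  ppp <- config$peptides_per_protein
  pep_choices <- seq(ppp[1], ppp[2])
  n_pep <- pep_choices[sample.int(length(pep_choices), nrow(proteins),
                                  replace = TRUE)]
  peptides <- tibble(
    accession = rep(proteins$accession, n_pep),
    peptide = random_peptide_sequences(sum(n_pep)),
    peptide_log_effect = rnorm(sum(n_pep), 0, config$peptide_log_sd),
    charge = sample(2:4, sum(n_pep), replace = TRUE,
                    prob = c(0.6, 0.3, 0.1))
  )

  # optionally duplicate some prey peptides under a second accession so the
  # rollup's shared-peptide exclusion has something to exclude
  if (config$shared_peptide_fraction > 0 && config$n_proteins >= 2) {
    prey_pep <- which(peptides$accession != config$bait_accession)
    n_shared <- floor(config$shared_peptide_fraction * length(prey_pep))
    if (n_shared > 0) {
      idx <- sample(prey_pep, n_shared)
      extra <- peptides[idx, ]
      extra$accession <- vapply(extra$accession, function(a) {
        sample(setdiff(prey_acc, a), 1)
      }, character(1))
      peptides <- bind_rows(peptides, extra)
    }
  }

  obs <- tidyr::crossing(peptides, runs)
  obs <- left_join(obs, proteins, by = "accession")
  is_test <- obs$group == groups[["test"]]
  log_int <- log(obs$scale) + obs$base_log + obs$peptide_log_effect +
    rnorm(nrow(obs), 0, config$base_log_sd) +
    is_test * log(fold[obs$accession])
  obs$intensity <- unname(exp(log_int))

  if (config$missingness_rate > 0) {
    keep <- obs$is_bait | (runif(nrow(obs)) >= config$missingness_rate)
    obs <- obs[keep, ]
  }

  peptide_table <- obs %>%
    select("run_id", "group", "accession", "description", "peptide",
           "charge", "intensity") %>%
    arrange(.data$run_id, .data$accession, .data$peptide, .data$charge)

  # true bait-normalized reference abundance: replicate noise has the same
  # log-normal mean in numerator and denominator, so it cancels in the ratio
  pep_sum <- peptides %>%
    group_by(.data$accession) %>%
    summarise(effect_sum = sum(exp(.data$peptide_log_effect)), .groups = "drop")
  bait_total <- exp(proteins$base_log[proteins$is_bait]) *
    pep_sum$effect_sum[pep_sum$accession == config$bait_accession]
  truth <- proteins %>%
    left_join(pep_sum, by = "accession") %>%
    mutate(
      true_fold_change = unname(fold[.data$accession]),
      true_mean_reference = exp(.data$base_log) * .data$effect_sum / bait_total
    ) %>%
    select("accession", "true_fold_change", "true_mean_reference")

  list(peptides = peptide_table, truth = truth)
}

#' Generate a null IP-MS experiment (no true differences)
#'
#' Identical to [simulate_ipms()] with the spiked set forced empty: every
#' protein's true fold change is 1. Used for false-positive calibration.
#'
#' @inheritParams simulate_ipms
#' @return As [simulate_ipms()].
#' @export
simulate_null_ipms <- function(config, seed = config$seed) {
  if (!inherits(config, "ipms_sim_config")) {
    abort("`config` must come from sim_config()", class = "ipmsdiff_config_error")
  }
  config$spiked_proteins <- numeric()
  simulate_ipms(config, seed = seed)
}

#' Summarise simulation ground truth
#'
#' One row per protein with its true fold change and whether it is truly
#' differential (fold change different from 1).
#'
#' @param truth The `truth` tibble from [simulate_ipms()].
#' @return A tibble with columns `accession`, `true_fold_change`,
#'   `true_mean_reference`, `is_differential`.
#' @export
truth_summary <- function(truth) {
  if (!is.data.frame(truth) || nrow(truth) == 0) {
    abort("`truth` must be a non-empty data frame", class = "ipmsdiff_input_error")
  }
  truth %>%
    as_tibble() %>%
    mutate(is_differential = .data$true_fold_change != 1)
}
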