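#' Hit-calling criteria
#'
#' The conjunctive rule under which a protein is called a differential
#' interactor: at least `min_quantified_peptides` unique peptides
#' quantified, AND a fold change at least `up_ratio` or at most
#' `down_ratio`, AND a two-sided p-value below `alpha`.
#'
#' @param min_quantified_peptides Minimum unique quantified peptides
#'   (default 2).
#' @param up_ratio,down_ratio Fold-change bounds (test/reference); a hit
#'   needs ratio >= `up_ratio` or <= `down_ratio`. Defaults 1.5 and 0.667,
#'   i.e. a 1.5-fold increase or decrease.
#' @param alpha Significance bound on the raw p-value (default 0.05).
#' @return A list of class `ipms_hit_criteria`.
#' @export
hit_criteria <- function(min_quantified_peptides = 2L,
                         up_ratio = 1.5,
                         down_ratio = 0.667,
                         alpha = 0.05) {
  if (!is.numeric(min_quantified_peptides) || min_quantified_peptides < 1) {
    abort("`min_quantified_peptides` must be a positive integer",
          class = "ipmsdiff_config_error")
  }
  if (!is.numeric(up_ratio) || !is.numeric(down_ratio) ||
      !(down_ratio < 1 && 1 < up_ratio)) {
    abort("need `down_ratio` < 1 < `up_ratio`", class = "ipmsdiff_config_error")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1)", class = "ipmsdiff_config_error")
  }
  structure(
    list(min_quantified_peptides = as.integer(min_quantified_peptides),
         up_ratio = up_ratio, down_ratio = down_ratio, alpha = alpha),
    class = "ipms_hit_criteria"
  )
}

#' Per-protein group means of normalized intensities
#'
#' Arithmetic means of the bait-normalized intensities across each group's
#' runs, the quantities the fold change is formed from.
#'
#' @param quant Normalized protein quantification tibble (after
#'   [bait_normalize()], usually after [replicate_presence_filter()]).
#' @param reference Label of the reference group; the other group label in
#'   the table is taken as the test group.
#' @return A tibble with one row per protein: `accession`, `description`,
#'   `total_peptides`, `quantified_peptides`, `mean_reference`, `mean_test`.
#' @export
group_means <- function(quant, reference) {
  if (!"normalized_intensity" %in% names(quant)) {
    abort("`quant` must be bait-normalized (missing normalized_intensity)",
          class = "ipmsdiff_input_error")
  }
  groups <- unique(quant$group)
  if (!reference %in% groups) {
    abort(sprintf("reference group '%s' not present in the table", reference),
          class = "ipmsdiff_input_error")
  }
  if (length(groups) != 2) {
    abort("exactly two groups are required", class = "ipmsdiff_input_error")
  }
  run_counts <- quant %>% distinct(.data$run_id, .data$group) %>% count(.data$group)
  if (any(run_counts$n < 2)) {
    abort("each group needs at least 2 runs", class = "ipmsdiff_input_error")
  }
  quant %>%
    mutate(role = if_else(.data$group == reference, "mean_reference", "mean_test")) %>%
    group_by(.data$accession, .data$description,
             .data$total_peptides, .data$quantified_peptides, .data$role) %>%
    summarise(m = mean(.data$normalized_intensity), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "role", values_from = "m") %>%
    select("accession", "description", "total_peptides", "quantified_peptides",
           "mean_reference", "mean_test")
}

#' Fold change (test over reference)
#'
#' @param mean_reference,mean_test Group mean normalized intensities
#'   (vectorized).
#' @return `mean_test / mean_reference`. A zero reference mean yields `NA`
#'   with a warning — the ratio is undefined, never silently infinite.
#' @export
#' @examples
#' fold_change(0.05596, 0.09804) # ~1.752
fold_change <- function(mean_reference, mean_test) {
  undefined <- !is.na(mean_reference) & mean_reference == 0
  if (any(undefined)) {
    warn(sprintf("%d protein(s) have zero reference mean: ratio undefined (NA)",
                 sum(undefined)))
  }
  out <- mean_test / mean_reference
  out[undefined] <- NA_real_
  out
}

#' Two-sample unpaired t-test (Student or Welch)
#'
#' Two-sided test of equal group means. The `"student"` variant pools the
#' variances (degrees of freedom `n1 + n2 - 2`); `"welch"` does not assume
#' equal variances and uses the Welch–Satterthwaite degrees of freedom.
#' The statistic is oriented as `reference - test`.
#'
#' Degenerate inputs: two constant, equal samples give `t = 0, p = 1`
#' (no evidence of a difference); zero pooled variance with unequal means
#' leaves the statistic undefined and raises an error.
#'
#' @param reference_values,test_values Numeric vectors, each of length >= 2.
#' @param variant `"student"` (default) or `"welch"`.
#' @return A one-row tibble with `t_statistic`, `df`, `p_value`.
#' @export
#' @examples
#' unpaired_t_test(c(1, 2, 3), c(2, 3, 4)) # t = -1.2247, df = 4
unpaired_t_test <- function(reference_values, test_values,
                            variant = c("student", "welch")) {
  variant <- match.arg(variant)
  x <- reference_values
  y <- test_values
  if (length(x) < 2 || length(y) < 2 || anyNA(x) || anyNA(y)) {
    abort("both samples need >= 2 non-missing values",
          class = "ipmsdiff_input_error")
  }
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      df <- if (variant == "student") length(x) + length(y) - 2 else NA_real_
      return(tibble(t_statistic = 0, df = df, p_value = 1))
    }
    abort("zero variance in both samples with unequal means: t undefined",
          class = "ipmsdiff_degenerate_error")
  }
  fit <- t.test(x, y, var.equal = (variant == "student"))
  tibble(t_statistic = unname(fit$statistic),
         df = unname(fit$parameter),
         p_value = fit$p.value)
}

# NA-propagating wrapper used per protein inside the pipeline
safe_t_test <- function(x, y, variant) {
  tryCatch(
    unpaired_t_test(x, y, variant),
    ipmsdiff_degenerate_error = function(e) {
      tibble(t_statistic = NA_real_, df = NA_real_, p_value = NA_real_)
    }
  )
}

#' Apply the conjunctive hit rule
#'
#' Flags each protein as a hit when all three conditions of `criteria`
#' hold: enough quantified peptides, fold change beyond the up or down
#' bound, and p-value below alpha. Rows with an undefined (NA) ratio or
#' p-value are never hits (a warning is emitted).
#'
#' @param results Tibble with columns `quantified_peptides`, `ratio`,
#'   `p_value`.
#' @param criteria An `ipms_hit_criteria` from [hit_criteria()].
#' @return `results` with a logical `is_hit` column added (replaced if
#'   already present).
#' @export
call_hits <- function(results, criteria = hit_criteria()) {
  if (!inherits(criteria, "ipms_hit_criteria")) {
    abort("`criteria` must come from hit_criteria()",
          class = "ipmsdiff_config_error")
  }
  needed <- c("quantified_peptides", "ratio", "p_value")
  missing_cols <- setdiff(needed, names(results))
  if (length(missing_cols) > 0) {
    abort(sprintf("`results` missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "ipmsdiff_input_error")
  }
  undefined <- is.na(results$ratio) | is.na(results$p_value)
  if (any(undefined)) {
    warn(sprintf("%d protein(s) with undefined ratio or p-value are not hits",
                 sum(undefined)))
  }
  mutate(results, is_hit = !undefined &
           .data$quantified_peptides >= criteria$min_quantified_peptides &
           (.data$ratio >= criteria$up_ratio | .data$ratio <= criteria$down_ratio) &
           .data$p_value < criteria$alpha)
}

#' Order a differential result table for reporting
#'
#' Rows sorted by p-value ascending (most significant first), ties broken
#' by accession lexicographically — the conventional presentation of an
#' IP-MS hit table.
#'
#' @param results Differential result tibble with `p_value` and
#'   `accession` columns.
#' @return The sorted tibble.
#' @export
build_result_table <- function(results) {
  if (!all(c("p_value", "accession") %in% names(results))) {
    abort("`results` must have p_value and accession columns",
          class = "ipmsdiff_input_error")
  }
  arrange(results, .data$p_value, .data$accession)
}

#' Differential analysis of a normalized protein table
#'
#' Computes, per protein: group means of the bait-normalized intensities,
#' the test/reference fold change, an unpaired t-test on the per-run
#' normalized values, a Benjamini–Hochberg adjusted p-value (reported for
#' information only; hit calling uses the raw p-value), and the
#' conjunctive hit flag. Tests are performed on the linear normalized
#' scale by default; `log_scale = TRUE` tests log-transformed values
#' instead (means and ratios are always reported on the linear scale).
#'
#' @inheritParams group_means
#' @inheritParams call_hits
#' @param variant t-test variant, `"student"` (default) or `"welch"`.
#' @param log_scale Test on natural-log normalized intensities.
#' @return A tibble ordered by [build_result_table()], one row per
#'   protein, with columns `accession`, `description`, `total_peptides`,
#'   `quantified_peptides`, `mean_reference`, `mean_test`, `ratio`,
#'   `t_statistic`, `df`, `p_value`, `p_adjusted`, `is_hit`.
#' @export
differential_results <- function(quant, reference,
                                 criteria = hit_criteria(),
                                 variant = c("student", "welch"),
                                 log_scale = FALSE) {
  variant <- match.arg(variant)
  means <- group_means(quant, reference)
  tests <- quant %>%
    mutate(role = if_else(.data$group == reference, "ref", "test"),
           value = if (log_scale) log(.data$normalized_intensity)
                   else .data$normalized_intensity) %>%
    group_by(.data$accession) %>%
    summarise(
      test = list(safe_t_test(.data$value[.data$role == "ref"],
                              .data$value[.data$role == "test"],
                              variant)),
      .groups = "drop"
    ) %>%
    tidyr::unnest("test")

  means %>%
    left_join(tests, by = "accession") %>%
    mutate(ratio = fold_change(.data$mean_reference, .data$mean_test),
           p_adjusted = p.adjust(.data$p_value, method = "BH")) %>%
    call_hits(criteria) %>%
    select("accession", "description", "total_peptides", "quantified_peptides",
           "mean_reference", "mean_test", "ratio", "t_statistic", "df",
           "p_value", "p_adjusted", "is_hit") %>%
    build_result_table()
}
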