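#' Compare densitometry measurements between two conditions
#'
#' Western-blot quantification: each lane's band signal is normalized to
#' the loading-control signal within the same lane, and the per-lane
#' ratios are compared between the two conditions with a two-sided
#' Student's t-test. Fewer than three lanes in a condition triggers a
#' warning (at least three independent replicates are expected).
#'
#' @param data Long-format tibble with columns `condition`, `signal`,
#'   `control_signal` and optionally `unit_id` (lane label, used in error
#'   messages). Exactly two conditions must be present.
#' @param reference Condition treated as the reference (first) group;
#'   defaults to the first condition in the table.
#' @return A list with `ratios` (the per-lane normalized ratios) and
#'   `stats`, a one-row tibble with the two group means, `t_statistic`,
#'   `df` and `p_value`.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   unit_id = paste0("lane", 1:6),
#'   condition = rep(c("WT", "KO"), each = 3),
#'   signal = c(2, 2, 2, 4, 5, 6),
#'   control_signal = c(1, 2, 4, 2, 2, 2))
#' densitometry_compare(d, reference = "WT")$stats
densitometry_compare <- function(data, reference = NULL) {
  needed <- c("condition", "signal", "control_signal")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("`data` missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "ipmsdiff_input_error")
  }
  if (!"unit_id" %in% names(data)) {
    data$unit_id <- paste0("lane", seq_len(nrow(data)))
  }
  conds <- unique(data$condition)
  if (length(conds) != 2) {
    abort("`data` must contain exactly two conditions",
          class = "ipmsdiff_input_error")
  }
  reference <- reference %||% conds[1]
  if (!reference %in% conds) {
    abort(sprintf("reference condition '%s' not present", reference),
          class = "ipmsdiff_input_error")
  }
  other <- setdiff(conds, reference)

  bad <- data$unit_id[is.na(data$control_signal) | data$control_signal <= 0]
  if (length(bad) > 0) {
    abort(sprintf("zero or missing loading control in lane(s) %s",
                  paste(bad, collapse = ", ")),
          class = "ipmsdiff_input_error")
  }
  sizes <- table(data$condition)
  if (any(sizes < 3)) {
    warn("fewer than 3 lanes in a condition; at least three independent replicates are expected")
  }

  ratios <- data %>%
    as_tibble() %>%
    mutate(ratio = .data$signal / .data$control_signal) %>%
    select("unit_id", "condition", "ratio")

  ref_r <- ratios$ratio[ratios$condition == reference]
  oth_r <- ratios$ratio[ratios$condition == other]
  tt <- unpaired_t_test(ref_r, oth_r, variant = "student")
  stats <- tibble(
    reference = reference, comparison = other,
    mean_reference = mean(ref_r), mean_comparison = mean(oth_r),
    t_statistic = tt$t_statistic, df = tt$df, p_value = tt$p_value
  )
  list(ratios = ratios, stats = stats)
}

#' Compare two telomere-intensity distributions (Q-FISH)
#'
#' Welch's unpaired two-sided t-test on per-spot telomere fluorescence
#' intensities from two genotypes — the variance of telomere-length
#' distributions typically differs between genotypes, hence Welch rather
#' than the pooled test. Delegates to [unpaired_t_test()] with the
#' `"welch"` variant.
#'
#' @param intensities_a,intensities_b Numeric vectors of spot intensities,
#'   each of length >= 2.
#' @return A one-row tibble with `t_statistic`, `df`
#'   (Welch–Satterthwaite) and `p_value`.
#' @export
qfish_compare <- function(intensities_a, intensities_b) {
  unpaired_t_test(intensities_a, intensities_b, variant = "welch")
}

#' Doubly normalized TCF reporter (Top/Fop) luciferase activity
#'
#' Firefly luciferase signal from the Top reporter (functional TCF sites)
#' is first normalized to the co-transfected Renilla signal in the same
#' well (transfection efficiency), then to the equally Renilla-normalized
#' activity of the Fop reporter (mutated TCF sites) under the same
#' treatment:
#' `(top_firefly / top_renilla) / (fop_firefly / fop_renilla)`.
#' All arguments are vectorized over replicate experiments.
#'
#' @param top_firefly,top_renilla Firefly and Renilla readings from the
#'   Top-transfected well.
#' @param fop_firefly,fop_renilla Firefly and Renilla readings from the
#'   Fop-transfected well.
#' @return The normalized activity (dimensionless).
#' @export
#' @examples
#' luciferase_normalize(1000, 100, 400, 80) # 2
luciferase_normalize <- function(top_firefly, top_renilla,
                                 fop_firefly, fop_renilla) {
  if (any(is.na(top_renilla) | top_renilla <= 0) ||
      any(is.na(fop_renilla) | fop_renilla <= 0)) {
    abort("Renilla readings must be positive", class = "ipmsdiff_input_error")
  }
  fop_ratio <- fop_firefly / fop_renilla
  if (any(is.na(fop_ratio) | fop_ratio <= 0)) {
    abort("Fop firefly/Renilla ratio must be positive",
          class = "ipmsdiff_input_error")
  }
  (top_firefly / top_renilla) / fop_ratio
}
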