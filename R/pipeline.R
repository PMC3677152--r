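#' Run the full differential IP-MS pipeline
#'
#' Executes the complete analysis on a peptide-ion table: charge filter →
#' unique-peptide protein rollup → per-run bait normalization → replicate
#' presence filter → group means, fold changes and t-tests → conjunctive
#' hit calling. Stage counts (records and proteins surviving each stage)
#' are recorded and, with `verbose = TRUE`, reported as messages.
#'
#' @param peptides Peptide-ion tibble (from [read_peptide_table()] or
#'   [simulate_ipms()]).
#' @param bait Bait protein accession.
#' @param reference Reference group label.
#' @param criteria Hit-calling thresholds from [hit_criteria()].
#' @param charges Allowed charge states (default 2:4).
#' @param scope Presence-filter scope, see [replicate_presence_filter()].
#' @param variant t-test variant (`"student"` default).
#' @param log_scale Test log-transformed normalized intensities.
#' @param verbose Emit per-stage messages.
#' @return An object of class `ipms_fit`: a list with `results` (the
#'   ordered differential table), `counts` (per-stage record/protein
#'   counts), and the call parameters. Use [tidy()] for the result table,
#'   [glance()] for a one-row summary, [autoplot()] for a volcano plot.
#' @export
#' @examples
#' sim <- simulate_ipms(sim_config(n_proteins = 20), seed = 7)
#' fit <- run_ipms_pipeline(sim$peptides, bait = "BAIT", reference = "WT")
#' glance(fit)
run_ipms_pipeline <- function(peptides, bait, reference,
                              criteria = hit_criteria(),
                              charges = 2:4,
                              scope = c("all_runs", "all_reference_runs",
                                        "per_group"),
                              variant = c("student", "welch"),
                              log_scale = FALSE,
                              verbose = FALSE) {
  scope <- match.arg(scope)
  variant <- match.arg(variant)
  say <- function(...) if (verbose) inform(sprintf(...))

  n_in <- nrow(peptides)
  charged <- filter_charge_states(peptides, allowed = charges)
  say("charge filter: %d of %d peptide-ion records retained", nrow(charged), n_in)

  quant <- rollup_protein_intensity(charged)
  n_prot <- n_distinct(quant$accession)
  say("rollup: %d proteins quantified", n_prot)

  quant <- bait_normalize(quant, bait)
  quant <- replicate_presence_filter(quant, scope = scope, reference = reference)
  n_kept <- n_distinct(quant$accession)
  say("presence filter (%s): %d of %d proteins retained", scope, n_kept, n_prot)

  results <- differential_results(quant, reference, criteria = criteria,
                                  variant = variant, log_scale = log_scale)
  say("hit calling: %d of %d proteins called hits", sum(results$is_hit), n_kept)

  structure(
    list(
      results = results,
      counts = tibble(
        stage = c("input_records", "charge_filtered_records",
                  "proteins_quantified", "proteins_retained", "hits"),
        n = c(n_in, nrow(charged), n_prot, n_kept, sum(results$is_hit))
      ),
      bait = bait, reference = reference, criteria = criteria,
      charges = charges, scope = scope, variant = variant,
      log_scale = log_scale
    ),
    class = "ipms_fit"
  )
}

#' @export
print.ipms_fit <- function(x, ...) {
  cat(sprintf("Differential IP-MS analysis (bait %s, reference group %s)\n",
              x$bait, x$reference))
  cat(sprintf("  %d proteins retained, %d hits (|ratio| bound %.3g/%.3g, p < %.3g, >= %d peptides)\n",
              x$counts$n[x$counts$stage == "proteins_retained"],
              x$counts$n[x$counts$stage == "hits"],
              x$criteria$up_ratio, x$criteria$down_ratio, x$criteria$alpha,
              x$criteria$min_quantified_peptides))
  print(head(x$results, 10))
  invisible(x)
}

#' @rdname run_ipms_pipeline
#' @param x,object An `ipms_fit`.
#' @param ... Unused.
#' @method tidy ipms_fit
#' @export
tidy.ipms_fit <- function(x, ...) {
  x$results
}

#' @rdname run_ipms_pipeline
#' @method glance ipms_fit
#' @export
glance.ipms_fit <- function(x, ...) {
  tibble(
    n_proteins = nrow(x$results),
    n_hits = sum(x$results$is_hit),
    n_up = sum(x$results$is_hit & x$results$ratio > 1, na.rm = TRUE),
    n_down = sum(x$results$is_hit & x$results$ratio < 1, na.rm = TRUE),
    alpha = x$criteria$alpha,
    up_ratio = x$criteria$up_ratio,
    down_ratio = x$criteria$down_ratio,
    min_quantified_peptides = x$criteria$min_quantified_peptides,
    variant = x$variant
  )
}

#' @rdname run_ipms_pipeline
#' @method autoplot ipms_fit
#' @export
autoplot.ipms_fit <- function(object, ...) {
  dat <- object$results %>%
    dplyr::filter(!is.na(.data$ratio), !is.na(.data$p_value))
  ggplot2::ggplot(dat, ggplot2::aes(x = log2(.data$ratio),
                                    y = -log10(.data$p_value),
                                    colour = .data$is_hit)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = log2(c(object$criteria$down_ratio,
                                            object$criteria$up_ratio)),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(object$criteria$alpha),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                                 name = "hit") +
    ggplot2::labs(x = "log2 fold change (test / reference)",
                  y = "-log10 p-value",
                  title = sprintf("Differential interactors of %s", object$bait)) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential result table
#'
#' Convenience wrapper for plotting a bare result tibble (e.g. the
#' published fixture) rather than an `ipms_fit`.
#'
#' @param results Differential result tibble with `ratio` and `p_value`
#'   (and optionally `is_hit`) columns.
#' @param criteria Thresholds drawn as dashed guides.
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, criteria = hit_criteria()) {
  if (!"is_hit" %in% names(results)) {
    results <- call_hits(results, criteria)
  }
  fit <- structure(list(results = results, criteria = criteria, bait = "bait"),
                   class = "ipms_fit")
  autoplot(fit)
}
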