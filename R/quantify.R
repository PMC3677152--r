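#' Keep peptide ions in the allowed charge states
#'
#' Label-free quantification typically restricts features to multicharged
#' ions; the default whitelist is 2+, 3+ and 4+.
#'
#' @param peptides Peptide-ion tibble (see [read_peptide_table()]).
#' @param allowed Integer vector of permitted charge states.
#' @return The subset of `peptides` whose `charge` is in `allowed`, order
#'   preserved. May be empty.
#' @export
#' @examples
#' tbl <- tibble::tibble(run_id = "r1", group = "WT", accession = "P1",
#'   description = "p", peptide = c("AAK", "CCK"), charge = c(1L, 2L),
#'   intensity = c(10, 20))
#' filter_charge_states(tbl)
filter_charge_states <- function(peptides, allowed = 2:4) {
  if (length(allowed) == 0) {
    abort("`allowed` must name at least one charge state",
          class = "ipmsdiff_input_error")
  }
  check_peptide_columns(peptides)
  dplyr::filter(peptides, .data$charge %in% allowed)
}

check_peptide_columns <- function(peptides, call_name = "peptide table") {
  needed <- c("run_id", "group", "accession", "peptide", "charge", "intensity")
  missing_cols <- setdiff(needed, names(peptides))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing column(s): %s", call_name,
                  paste(missing_cols, collapse = ", ")),
          class = "ipmsdiff_input_error")
  }
  invisible(peptides)
}

#' Roll peptide-ion intensities up to protein intensities
#'
#' For each protein and run, sums the intensities of that protein's
#' *unique* peptide ions — peptide sequences attributed to two or more
#' protein accessions anywhere in the table are excluded from every sum.
#' Two peptide counts are reported per protein: `total_peptides`, the
#' distinct peptide sequences observed for the protein anywhere in the
#' table, and `quantified_peptides`, the distinct unique sequences that
#' contribute to its sums.
#'
#' A `(protein, run)` pair with no observed unique peptide ion yields no
#' row: absence means unobserved, which the presence filter treats as not
#' recovered.
#'
#' @param peptides Charge-filtered peptide-ion tibble.
#' @return A protein quantification tibble with one row per observed
#'   `(accession, run_id)`: `accession`, `description`, `run_id`, `group`,
#'   `summed_intensity`, `total_peptides`, `quantified_peptides`.
#' @export
rollup_protein_intensity <- function(peptides) {
  check_peptide_columns(peptides)
  if (nrow(peptides) == 0) {
    return(tibble(accession = character(), description = character(),
                  run_id = character(), group = character(),
                  summed_intensity = numeric(), total_peptides = integer(),
                  quantified_peptides = integer()))
  }
  shared <- peptides %>%
    distinct(.data$accession, .data$peptide) %>%
    count(.data$peptide) %>%
    dplyr::filter(.data$n > 1) %>%
    pull(.data$peptide)

  counts <- peptides %>%
    group_by(.data$accession) %>%
    summarise(
      total_peptides = n_distinct(.data$peptide),
      quantified_peptides = n_distinct(.data$peptide[!(.data$peptide %in% shared)]),
      .groups = "drop"
    )

  descriptions <- peptides %>%
    distinct(.data$accession, .data$description) %>%
    group_by(.data$accession) %>%
    summarise(description = first(.data$description), .groups = "drop")

  peptides %>%
    dplyr::filter(!(.data$peptide %in% shared)) %>%
    group_by(.data$accession, .data$run_id, .data$group) %>%
    summarise(summed_intensity = sum(.data$intensity), .groups = "drop") %>%
    left_join(descriptions, by = "accession") %>%
    left_join(counts, by = "accession") %>%
    select("accession", "description", "run_id", "group",
           "summed_intensity", "total_peptides", "quantified_peptides") %>%
    arrange(.data$accession, .data$run_id)
}

#' Normalize protein intensities to the bait, per run
#'
#' Divides every protein's summed intensity in a run by the bait protein's
#' summed intensity in that same run. This cancels per-run global scale
#' differences (IP efficiency, loading): multiplying every intensity in a
#' run by a positive constant leaves the normalized values unchanged, and
#' the bait itself is exactly 1 in every run.
#'
#' @param quant Protein quantification tibble from
#'   [rollup_protein_intensity()].
#' @param bait_accession Accession of the bait protein. It must have
#'   positive summed intensity in every run of the table; normalization is
#'   undefined otherwise and the offending run is named in the error.
#' @return `quant` with a `normalized_intensity` column added.
#' @export
bait_normalize <- function(quant, bait_accession) {
  if (!all(c("accession", "run_id", "summed_intensity") %in% names(quant))) {
    abort("`quant` must have accession, run_id and summed_intensity columns",
          class = "ipmsdiff_input_error")
  }
  runs <- unique(quant$run_id)
  bait <- quant %>%
    dplyr::filter(.data$accession == bait_accession, .data$summed_intensity > 0) %>%
    select("run_id", bait_intensity = "summed_intensity")
  bad <- setdiff(runs, bait$run_id)
  if (length(bad) > 0) {
    abort(sprintf(
      "bait '%s' absent or zero in run(s) %s: bait normalization undefined",
      bait_accession, paste(bad, collapse = ", ")),
      class = "ipmsdiff_bait_error")
  }
  quant %>%
    left_join(bait, by = "run_id") %>%
    mutate(normalized_intensity = .data$summed_intensity / .data$bait_intensity) %>%
    select(-"bait_intensity")
}

#' Keep proteins recovered in the required runs
#'
#' Retains proteins observed (positive summed intensity) in every run the
#' scope demands. The default, `"all_runs"`, requires recovery in every
#' run of both groups — the strictest reading of "recovered in all
#' experiments". `"all_reference_runs"` requires recovery only in the
#' reference group's runs; `"per_group"` requires recovery in every run of
#' at least one group.
#'
#' The run universe is taken from the runs present in `quant`; after
#' [bait_normalize()] the bait guarantees every run appears.
#'
#' @param quant Protein quantification tibble.
#' @param scope One of `"all_runs"`, `"all_reference_runs"`, `"per_group"`.
#' @param reference Reference group label; required for
#'   `"all_reference_runs"`.
#' @return The filtered tibble.
#' @export
replicate_presence_filter <- function(quant,
                                      scope = c("all_runs", "all_reference_runs",
                                                "per_group"),
                                      reference = NULL) {
  scope <- match.arg(scope)
  observed <- quant %>%
    dplyr::filter(.data$summed_intensity > 0) %>%
    distinct(.data$accession, .data$run_id, .data$group)
  run_universe <- quant %>% distinct(.data$run_id, .data$group)

  keep <- switch(
    scope,
    all_runs = {
      observed %>%
        count(.data$accession) %>%
        dplyr::filter(.data$n == nrow(run_universe)) %>%
        pull(.data$accession)
    },
    all_reference_runs = {
      if (is.null(reference)) {
        abort("`reference` is required for scope \"all_reference_runs\"",
              class = "ipmsdiff_input_error")
      }
      n_ref <- sum(run_universe$group == reference)
      if (n_ref == 0) {
        abort(sprintf("no runs belong to reference group '%s'", reference),
              class = "ipmsdiff_input_error")
      }
      observed %>%
        dplyr::filter(.data$group == reference) %>%
        count(.data$accession) %>%
        dplyr::filter(.data$n == n_ref) %>%
        pull(.data$accession)
    },
    per_group = {
      group_sizes <- count(run_universe, .data$group, name = "n_runs")
      observed %>%
        count(.data$accession, .data$group) %>%
        left_join(group_sizes, by = "group") %>%
        dplyr::filter(.data$n == .data$n_runs) %>%
        distinct(.data$accession) %>%
        pull(.data$accession)
    }
  )
  dplyr::filter(quant, .data$accession %in% keep)
}
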