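peptide_table_cols <- c("run_id", "group", "accession", "description",
                        "peptide", "charge", "intensity")

#' Read a tab-separated peptide-ion intensity table
#'
#' Expects a UTF-8 TSV with header columns `run_id`, `group`, `accession`,
#' `description`, `peptide`, `charge`, `intensity` — one row per observed
#' peptide ion per run. A blank intensity cell means the ion was not
#' observed in that run; such rows are dropped. Malformed rows (negative
#' intensity, non-positive or non-integer charge) raise an error citing
#' the offending file line.
#'
#' @param path Path to the TSV file.
#' @return A tibble of peptide-ion records.
#' @export
read_peptide_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "ipmsdiff_io_error")
  }
  # column validation below raises typed errors; readr's own complaints
  # about absent columns would duplicate them
  raw <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      run_id = readr::col_character(),
      group = readr::col_character(),
      accession = readr::col_character(),
      description = readr::col_character(),
      peptide = readr::col_character(),
      charge = readr::col_double(),
      intensity = readr::col_double()
    ),
    progress = FALSE
  ))
  missing_cols <- setdiff(peptide_table_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("peptide table %s is missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = "ipmsdiff_io_error")
  }
  raw <- raw[peptide_table_cols]
  # file line = row index + header line
  raw$.line <- seq_len(nrow(raw)) + 1L

  bad <- raw$.line[!is.na(raw$intensity) & raw$intensity < 0]
  if (length(bad) > 0) {
    abort(sprintf("negative intensity on line %s of %s",
                  paste(bad, collapse = ", "), path),
          class = "ipmsdiff_io_error")
  }
  bad <- raw$.line[is.na(raw$charge) | raw$charge < 1 |
                     raw$charge != as.integer(raw$charge)]
  if (length(bad) > 0) {
    abort(sprintf("charge must be a positive integer; offending line %s of %s",
                  paste(bad, collapse = ", "), path),
          class = "ipmsdiff_io_error")
  }
  raw %>%
    dplyr::filter(!is.na(.data$intensity)) %>%
    mutate(charge = as.integer(.data$charge)) %>%
    select(-".line")
}

#' Write a peptide-ion table as TSV
#'
#' Writes the format [read_peptide_table()] reads; a write/read round trip
#' reproduces the records.
#'
#' @param peptides Peptide-ion tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  check_peptide_columns(peptides)
  readr::write_tsv(peptides[peptide_table_cols], path, progress = FALSE)
  invisible(path)
}

#' Write a differential result table as TSV
#'
#' Deterministic byte output for fixed input: stable column order and
#' fixed 5-decimal formatting of the numeric summary columns, mirroring
#' the conventional presentation of IP-MS hit tables.
#'
#' @param results Differential result tibble (see
#'   [differential_results()]), ordered by [build_result_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(results, path) {
  cols <- c("accession", "description", "total_peptides", "quantified_peptides",
            "mean_reference", "mean_test", "p_value", "ratio", "is_hit")
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols) > 0) {
    abort(sprintf("`results` missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "ipmsdiff_io_error")
  }
  fmt <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 5, format = "f"))
  out <- results %>%
    as_tibble() %>%
    mutate(across(c("mean_reference", "mean_test", "p_value", "ratio"), fmt)) %>%
    select(dplyr::all_of(cols))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' The published beta-catenin IP-MS result table
#'
#' The nine-protein differential result table from a label-free IP-MS
#' comparison of beta-catenin interactors between wild-type and
#' telomerase-null (mTert-/-) mouse embryonic stem cells: per protein, the
#' peptide counts, the group-averaged bait-normalized intensities
#' (WT = reference, KO = test), the t-test p-value and the KO/WT ratio.
#' Shipped as a plain-text fixture; the underlying replicate-level
#' intensities were not published, so p-values cannot be recomputed from
#' this table, but ratios, orderings and hit calls can.
#'
#' @return A tibble with columns `accession`, `description`,
#'   `total_peptides`, `quantified_peptides`, `mean_reference`,
#'   `mean_test`, `p_value`, `ratio`.
#' @export
#' @examples
#' ipms_table1() |> call_hits() |> dplyr::select(accession, ratio, is_hit)
ipms_table1 <- function() {
  path <- system.file("extdata", "betacatenin_ipms_table1.tsv",
                      package = "ipmsdiff", mustWork = TRUE)
  readr::read_tsv(
    path,
    col_types = readr::cols(
      accession = readr::col_character(),
      description = readr::col_character(),
      total_peptides = readr::col_integer(),
      quantified_peptides = readr::col_integer(),
      mean_reference = readr::col_double(),
      mean_test = readr::col_double(),
      p_value = readr::col_double(),
      ratio = readr::col_double()
    ),
    progress = FALSE
  )
}
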