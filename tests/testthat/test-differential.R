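# independent closed-form oracle for the pooled two-sample t-test:
# statistic from the pooled-variance formula, two-sided p from the
# regularized incomplete beta function
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = pbeta(df / (df + t^2), df / 2, 1 / 2))
}

# exhaustive relabeling distribution of |t| for n = 3 + 3
perm_p_oracle <- function(x, y) {
  pool <- c(x, y)
  t_obs <- abs(pooled_t_oracle(x, y)$t)
  labs <- utils::combn(6, 3)
  t_all <- apply(labs, 2, function(i) abs(pooled_t_oracle(pool[i], pool[-i])$t))
  mean(t_all >= t_obs - 1e-12)
}

test_that("group means are arithmetic means of normalized intensities per group", {
  quant <- tibble::tibble(
    accession = "P1", description = "p",
    run_id = c("WT_1", "WT_2", "WT_3", "KO_1", "KO_2", "KO_3"),
    group = rep(c("WT", "KO"), each = 3),
    summed_intensity = 1,
    normalized_intensity = c(0.1, 0.2, 0.3, 0.2, 0.2, 0.2),
    total_peptides = 3L, quantified_peptides = 3L
  )
  m <- group_means(quant, reference = "WT")
  expect_equal(m$mean_reference, 0.2)
  expect_equal(m$mean_test, 0.2)
  one_run <- dplyr::filter(quant, run_id %in% c("WT_1", "KO_1", "KO_2"))
  expect_error(group_means(one_run, "WT"), "at least 2",
               class = "ipmsdiff_input_error")
  expect_error(group_means(quant, "XX"), class = "ipmsdiff_input_error")
})

test_that("fold change is test over reference; zero reference is NA with a warning", {
  expect_equal(fold_change(0.05596, 0.09804), 0.09804 / 0.05596)
  expect_equal(fold_change(2, 2), 1)
  expect_warning(r <- fold_change(c(0, 1), c(5, 2)), "undefined")
  expect_identical(r, c(NA_real_, 2))
})

test_that("student t-test matches the pooled closed form and incomplete-beta p", {
  out <- unpaired_t_test(c(1, 2, 3), c(2, 3, 4), variant = "student")
  expect_equal(out$t_statistic, -sqrt(3) / sqrt(2), tolerance = 1e-10)
  expect_equal(out$df, 4)
  expect_equal(out$p_value, 0.287864134727, tolerance = 1e-8)

  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(3 + i %% 3); y <- rnorm(4, mean = 0.5)
    ours <- unpaired_t_test(x, y, "student")
    orac <- pooled_t_oracle(x, y)
    expect_equal(ours$t_statistic, orac$t, tolerance = 1e-10)
    expect_equal(ours$df, orac$df)
    expect_equal(ours$p_value, orac$p, tolerance = 1e-10)
  }
})

test_that("degenerate samples: identical -> t 0 p 1; zero variance unequal -> error", {
  out <- unpaired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(out$t_statistic, 0)
  expect_equal(out$p_value, 1)
  flat <- unpaired_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(flat$t_statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(unpaired_t_test(c(0, 0, 0), c(1, 1, 1)),
               class = "ipmsdiff_degenerate_error")
  expect_error(unpaired_t_test(1, c(1, 2)), class = "ipmsdiff_input_error")
})

test_that("welch variant matches the hand-computed Welch-Satterthwaite formula", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
  out <- unpaired_t_test(x, y, variant = "welch")
  v1 <- var(x) / 4; v2 <- var(y) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df_hand <- (v1 + v2)^2 / (v1^2 / 3 + v2^2 / 3)
  expect_equal(out$t_statistic, t_hand, tolerance = 1e-10)
  expect_equal(out$df, df_hand, tolerance = 1e-10)
  expect_equal(out$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)
})

test_that("welch p converges to student p for equal variances at large n", {
  set.seed(7)
  x <- rnorm(400); y <- rnorm(400, mean = 0.1)
  s <- unpaired_t_test(x, y, "student")
  w <- unpaired_t_test(x, y, "welch")
  expect_equal(w$p_value, s$p_value, tolerance = 1e-3)
})

test_that("analytic student p agrees with the exhaustive 20-relabeling distribution", {
  set.seed(17)
  p_analytic <- p_perm <- numeric(25)
  for (i in 1:25) {
    x <- rnorm(3); y <- rnorm(3, mean = runif(1, 0, 2))
    p_analytic[i] <- unpaired_t_test(x, y, "student")$p_value
    p_perm[i] <- perm_p_oracle(x, y)
  }
  # permutation p is discrete on multiples of 1/20 (and >= 2/20 by sign
  # symmetry); demand rank agreement and bounded deviation
  expect_gt(cor(p_analytic, p_perm, method = "spearman"), 0.9)
  expect_lt(max(abs(p_analytic - p_perm)), 0.2)
})

test_that("the conjunctive hit rule is applied as stated", {
  crit <- hit_criteria()
  base <- tibble::tibble(quantified_peptides = 10L, ratio = 1.0, p_value = 0.9)
  expect_false(call_hits(base, crit)$is_hit)
  cases <- tibble::tibble(
    quantified_peptides = c(35L, 17L, 2L, 1L, 5L, 5L),
    ratio = c(1.75192, 0.81088, 0.40295, 2.0, 1.6, 0.5),
    p_value = c(0.03139, 0.01504, 0.02990, 0.001, 0.2, 0.04)
  )
  expect_equal(call_hits(cases, crit)$is_hit,
               c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_warning(
    und <- call_hits(tibble::tibble(quantified_peptides = 5L, ratio = NA_real_,
                                    p_value = 0.01), crit),
    "undefined")
  expect_false(und$is_hit)
})

test_that("hit criteria validate their bounds", {
  expect_error(hit_criteria(up_ratio = 0.9), class = "ipmsdiff_config_error")
  expect_error(hit_criteria(down_ratio = 1.2), class = "ipmsdiff_config_error")
  expect_error(hit_criteria(alpha = 0), class = "ipmsdiff_config_error")
  expect_error(hit_criteria(min_quantified_peptides = 0),
               class = "ipmsdiff_config_error")
})

test_that("result tables sort by p ascending with accession tie-break", {
  tbl <- tibble::tibble(accession = c("B", "A", "C"),
                        p_value = c(0.02, 0.02, 0.001))
  out <- build_result_table(tbl)
  expect_equal(out$accession, c("C", "A", "B"))
  one <- tibble::tibble(accession = "X", p_value = 0.5)
  expect_equal(build_result_table(one), one)
})

test_that("tightening criteria never increases the hit count", {
  sim <- simulate_ipms(small_config(
    spiked_proteins = c(PROT0001 = 3, PROT0002 = 0.4, PROT0003 = 1.8)),
    seed = 13)
  quant <- sim$peptides |>
    filter_charge_states() |>
    rollup_protein_intensity() |>
    bait_normalize("BAIT") |>
    replicate_presence_filter()
  hits <- function(crit) sum(differential_results(quant, "WT", crit)$is_hit)
  base <- hits(hit_criteria())
  expect_lte(hits(hit_criteria(up_ratio = 2.5, down_ratio = 1 / 2.5)), base)
  expect_lte(hits(hit_criteria(alpha = 0.01)), base)
  expect_lte(hits(hit_criteria(min_quantified_peptides = 4)), base)
})

test_that("swapping group roles inverts ratios and preserves p-values", {
  sim <- simulate_ipms(small_config(spiked_proteins = c(PROT0001 = 2)), seed = 19)
  quant <- sim$peptides |>
    filter_charge_states() |>
    rollup_protein_intensity() |>
    bait_normalize("BAIT") |>
    replicate_presence_filter()
  fwd <- differential_results(quant, reference = "WT")
  rev <- differential_results(quant, reference = "KO")
  merged <- dplyr::inner_join(fwd, rev, by = "accession",
                              suffix = c("_fwd", "_rev"))
  expect_equal(merged$ratio_rev, 1 / merged$ratio_fwd, tolerance = 1e-10)
  expect_equal(merged$p_value_rev, merged$p_value_fwd, tolerance = 1e-10)
})
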