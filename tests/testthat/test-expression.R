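test_that("TMM factors behave on constructed libraries", {
  set.seed(90)
  base <- matrix(rnbinom(500 * 4, mu = 100, size = 10), 500, 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
  # identical libraries: all factors 1
  same <- cbind(base[, 1], base[, 1], base[, 1])
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(tmm_factors(same)), rep(1, 3))

  # pure depth difference (2x), no composition change: factors stay ~1
  doubled <- cbind(base, 2L * base[, 1])
  colnames(doubled) <- paste0("s", 1:5)
  f <- tmm_factors(doubled)
  expect_equal(unname(f), rep(1, 5), tolerance = 0.01)

  # geometric mean exactly 1
  skewed <- base; skewed[1:50, 1] <- skewed[1:50, 1] * 30L
  f2 <- tmm_factors(skewed)
  expect_equal(exp(mean(log(f2))), 1)
  expect_error(tmm_factors(cbind(base[, 1], 0L)), "zero total")
})

test_that("log-CPM uses the natural log and is depth-invariant", {
  counts <- matrix(c(1L, 999999L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  lc <- log_cpm(counts, factors = c(s1 = 1), pseudocount = 0)
  expect_equal(lc["a", 1], log(1))  # count 1 in a 1e6 library -> CPM 1
  x <- matrix(c(10L, 90L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  lx <- log_cpm(x, factors = c(s1 = 1), pseudocount = 0)
  expect_equal(lx["a", 1], log(10 / 100 * 1e6))
  # doubling counts and effective depth together changes nothing
  l2 <- log_cpm(2L * x, factors = c(s1 = 1), pseudocount = 0)
  expect_equal(l2["a", 1], lx["a", 1])
})

test_that("per-gene variance change respects lots and recovers the generating
           variance factor", {
  cm <- simulate_expression_counts(n_genes = 300, seed = 91)
  lc <- log_cpm(cm)
  vc <- per_gene_variance_change(lc, cm$samples)
  expect_equal(colnames(vc$F), c("anc1_vs_evo1", "anc2_vs_evo2"))
  # identical samples in both roles give F = 1
  idself <- per_gene_variance_change(lc, cm$samples,
                                     pairing = list(c("anc1", "anc1")))
  expect_equal(unname(idself$F[, 1]), rep(1, 300))

  # generator oracle: all genes with evolved biological variance scaled by
  # 0.84 -> median per-gene F near 0.84 at large n and high expression
  cm2 <- simulate_expression_counts(
    n_genes = 1500, design = c(anc1 = 250L, evo1 = 250L),
    de_fraction = 0, variance_factor = 0.84, var_factor_genes = "all",
    dispersion_model = disp_constant(0.09),
    batch_effect = list(sd = 0, batches = c(anc1 = "lot1", evo1 = "lot1")),
    seed = 92)
  lc2 <- log_cpm(cm2)
  vc2 <- per_gene_variance_change(lc2, cm2$samples)
  hi <- cm2$true_params$mu > 200
  expect_equal(median(vc2$F[hi, 1]), 0.84, tolerance = 0.05)
})

test_that("jackknife variance intervals are sane and cover at the nominal
           rate", {
  cst <- jackknife_ci(rep(2, 10))
  expect_equal(cst$estimate, 0)
  expect_equal(cst$lower, 0)
  expect_equal(cst$upper, 0)
  expect_error(jackknife_ci(c(1, 2)), "at least 3")

  set.seed(93)
  x <- rnorm(20, 0, 2)
  ci <- jackknife_ci(x)
  expect_equal(ci$estimate, var(x))     # pseudovalue mean = unbiased variance
  expect_lt(ci$lower, ci$estimate)
  expect_gt(ci$upper, ci$estimate)

  cover <- vapply(seq_len(1000), function(i) {
    ci <- jackknife_ci(rnorm(20, 0, 1.5))
    ci$lower <= 1.5^2 && 1.5^2 <= ci$upper
  }, logical(1))
  expect_lt(abs(mean(cover) - 0.95), 0.03)
})

test_that("the CV^2 partition is exact, Poisson-limited and recovers the
           generating dispersion", {
  cm <- simulate_expression_counts(
    n_genes = 1200, design = c(anc1 = 50L, anc2 = 50L),
    de_fraction = 0, dispersion_model = disp_constant(0.04),
    batch_effect = list(sd = 0, batches = c(anc1 = "lot1", anc2 = "lot1")),
    seed = 94)
  cv <- cv_partition(cm, shrink = 0)
  expect_true(all(cv$total_cv2 >= 0, na.rm = TRUE))
  # Eq-style identity: total = technical + biological wherever the raw
  # biological component is non-negative
  raw_bio <- cv$total_cv2 - cv$technical_cv2
  ok <- !cv$flagged & raw_bio >= 0
  expect_equal(cv$technical_cv2[ok] + cv$biological_cv2[ok],
               cv$total_cv2[ok])
  # high-count genes: technical component vanishes
  hi <- !cv$flagged & cv$mean_ncount >= 1e4
  expect_true(all(cv$technical_cv2[hi] <= 1e-4))
  # NB generator with dispersion 0.04 at n = 50: median BCV^2 within 25%
  med <- median(cv$biological_cv2[!cv$flagged & cv$mean_ncount > 100])
  expect_lt(abs(med - 0.04) / 0.04, 0.25)
  expect_error(cv_partition(cm, shrink = 2), "shrink")
})

test_that("the technical share of CV^2 shrinks as sample size grows", {
  share <- vapply(c(5, 10, 22, 50), function(n) {
    cm <- simulate_expression_counts(
      n_genes = 500, design = c(anc1 = as.integer(n)),
      de_fraction = 0, dispersion_model = disp_constant(0.06),
      batch_effect = list(sd = 0, batches = c(anc1 = "lot1")),
      library_sizes = list(mean = 2e5 * n, sdlog = 0.1),
      seed = 95)
    cv <- cv_partition(cm, shrink = 0)
    mean((cv$technical_cv2 / cv$total_cv2)[!cv$flagged & cv$total_cv2 > 0],
         na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(share) < 0))
})

test_that("DE vs non-DE comparison is calibrated and detects variance-factor
           differences", {
  # trivial: identical F in both classes -> equal medians, p = 1
  Fv <- rep(c(0.8, 0.9), 50)
  lab <- rep(c(TRUE, FALSE), each = 50)
  r <- compare_de_vs_nonde(rep(0.85, 100), lab)
  expect_equal(r$median_F_de, r$median_F_nonde)
  expect_false(r$significant)

  # null calibration on random labels over a homogeneous generator
  set.seed(96)
  hits <- vapply(seq_len(400), function(i) {
    Fg <- rnorm(200, 0.9, 0.15)
    compare_de_vs_nonde(Fg, seq_len(200) %in% sample.int(200, 40))$significant
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.035)

  # positive control: DE genes generated at variance factor 0.5
  cm <- simulate_expression_counts(
    n_genes = 800, de_fraction = 0.3, mean_shift_sd = 0,
    variance_factor = 0.5, var_factor_genes = "de",
    dispersion_model = disp_constant(0.09), seed = 97)
  res <- analyze_expression(cm, de_label = cm$de_label)
  expect_lt(res$comparison[[1]]$t_p_value, 0.05)
  expect_lt(res$comparison[[1]]$median_F_de,
            res$comparison[[1]]$median_F_nonde)
})

test_that("stand-in DE calls control the FDR and find 1-SD shifts", {
  # null data: no true DE -> (almost) no calls
  cm0 <- simulate_expression_counts(n_genes = 1000, de_fraction = 0,
                                    seed = 98)
  lc0 <- log_cpm(cm0)
  calls0 <- de_call_standin(lc0, cm0$samples)
  expect_lt(mean(calls0), 0.02)

  # 1-SD shifts at n ~ 20 per population: majority of true DE recovered
  cm1 <- simulate_expression_counts(n_genes = 1000, de_fraction = 0.2,
                                    mean_shift_sd = 1, seed = 99)
  lc1 <- log_cpm(cm1)
  calls1 <- de_call_standin(lc1, cm1$samples)
  expect_gt(mean(calls1[cm1$de_label]), 0.5)
  expect_lt(mean(calls1[!cm1$de_label]), 0.1)

  # user-supplied labels pass through analyze_expression untouched
  res <- analyze_expression(cm1, de_label = cm1$de_label)
  expect_identical(res$de_label, cm1$de_label)
})

test_that("replicate ancestral variance estimates correlate across a
           heterogeneous transcriptome", {
  # heterogeneous per-gene dispersions (wide log-normal), as in real
  # transcriptomes where BCVs span an order of magnitude
  cm <- simulate_expression_counts(n_genes = 5000,
                                   design = c(anc1 = 20L, anc2 = 20L),
                                   de_fraction = 0,
                                   dispersion_model =
                                     disp_lognormal(log(0.09), 0.8),
                                   batch_effect = list(
                                     sd = 0.05,
                                     batches = c(anc1 = "lot1",
                                                 anc2 = "lot2")),
                                   seed = 100)
  lc <- log_cpm(cm)
  v1 <- adaptarch:::row_vars(lc[, cm$samples$population == "anc1"])
  v2 <- adaptarch:::row_vars(lc[, cm$samples$population == "anc2"])
  expect_gt(cor(v1, v2, method = "spearman"), 0.7)
})
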