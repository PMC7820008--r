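test_that("Fisher-Z averaging has the stated closed form and symmetries", {
  expect_equal(fisher_average(rep(0.7, 5))$r_mean, 0.7, tolerance = 1e-12)
  expect_equal(fisher_average(c(0.5, -0.5))$r_mean, 0, tolerance = 1e-12)
  expect_equal(fisher_average(c(0.9, 0.3))$r_mean,
               tanh((atanh(0.9) + atanh(0.3)) / 2), tolerance = 1e-12)
  expect_equal(fisher_average(c(0.9, 0.3))$r_mean, 0.71182295, tolerance = 1e-6)
  set.seed(19)
  r <- runif(20, -0.9, 0.9)
  expect_lte(abs(fisher_average(r)$r_mean), max(abs(r)))
  expect_error(fisher_average(c(0.5, 1)), "< 1")
})

test_that("Rueger areas apply the two-threshold conjunction over components", {
  # all 18 channels highly significant: one all-channel significant area
  p <- stats::setNames(rep(0.001, 18), montage_channels())
  res <- rueger_test(p)
  expect_equal(nrow(res), 1)
  expect_equal(res$size, 18)
  expect_true(res$significant)

  # 5-member contiguous area: 2/5 at 0.017 and 3/5 at 0.025 -> significant
  p <- stats::setNames(rep(0.5, 18), montage_channels())
  p[c("F3", "Fz", "F4", "C3", "C4", "Cz")] <-
    c(0.01, 0.016, 0.02, 0.03, 0.04, 0.2)
  res <- rueger_test(p)
  expect_equal(nrow(res), 1)
  expect_equal(res$size, 5)
  expect_equal(res$n_p017, 2)
  expect_equal(res$n_p025, 3)
  expect_true(res$significant)

  # descriptive but never stringent: areas exist, none significant
  p <- stats::setNames(rep(0.04, 18), montage_channels())
  res <- rueger_test(p)
  expect_true(nrow(res) >= 1)
  expect_false(any(res$significant))
  expect_true(all(res$n_p017 == 0) && all(res$n_p025 == 0))

  expect_error(rueger_test(c(Pz = 0.01)), "absent from adjacency")
})

test_that("rueger_test matches exhaustive flood-fill enumeration on small montages", {
  adj <- tibble::tibble(from = c("A", "B", "C", "E"),
                        to   = c("B", "C", "D", "F"))
  set.seed(23)
  for (i in 1:50) {
    p <- stats::setNames(runif(6), c("A", "B", "C", "D", "E", "F"))
    res <- rueger_test(p, adj)
    sig <- names(p)[p < 0.05]
    oracle <- components_bruteforce(sig, adj)
    expect_equal(length(oracle), nrow(res))
    got <- lapply(res$area, identity)
    expect_setequal(vapply(got, paste, "", collapse = "+"),
                    vapply(oracle, paste, "", collapse = "+"))
    for (comp in oracle) {
      row <- which(vapply(got, identical, TRUE, sort(comp)))
      k <- length(comp)
      expect_equal(res$n_p017[row], sum(p[comp] <= 0.05 / 3))
      expect_equal(res$significant[row],
                   sum(p[comp] <= 0.05 / 3) >= ceiling(k / 3) &&
                     sum(p[comp] <= 0.05 / 2) >= ceiling(k / 2))
    }
  }
})

test_that("the normality gate picks the right test and detects planted shifts", {
  set.seed(29)
  x <- rnorm(100); y <- 0.5 * x + rnorm(100)
  expect_equal(gated_association(x, y)$test, "Pearson")
  expect_equal(gated_association(x, exp(y))$test, "Spearman")

  g <- rep(c("a", "b"), each = 100)
  v <- exp(c(rnorm(100), rnorm(100) + 1))  # lognormal, 1 SD latent shift
  res <- gated_association(v, group = g)
  expect_equal(res$test, "Mann-Whitney")
  expect_lt(res$p, 0.05)
  expect_gt(res$effect_size, 0)

  vn <- c(rnorm(100), rnorm(100) + 1)
  resn <- gated_association(vn, group = g)
  expect_equal(resn$test, "t")
  expect_lt(resn$p, 0.05)

  expect_error(gated_association(rep(1, 20), rnorm(20)), "constant")
  expect_error(gated_association(x), "exactly one")
})

test_that("independent-correlation comparison follows the Fisher z closed form", {
  expect_equal(compare_independent_correlations(0.5, 30, 0.5, 50)$p_difference, 1)
  a <- compare_independent_correlations(0.6, 40, 0.2, 80)
  b <- compare_independent_correlations(0.2, 80, 0.6, 40)
  expect_equal(a$p_difference, b$p_difference, tolerance = 1e-12)
  expect_equal(a$z, -b$z, tolerance = 1e-12)
  # frozen closed-form value for r1=.44 (n=79), r2=.40 (n=60)
  expect_equal(compare_independent_correlations(0.44, 79, 0.40, 60)$p_difference,
               0.7815778, tolerance = 1e-6)
  expect_error(compare_independent_correlations(0.5, 3, 0.5, 50), "n >= 4")
})

test_that("the hypothesis battery recovers planted cohort effects", {
  co <- synth_cohort(n_subjects = 170, seed = 37)
  res <- run_hypotheses(co$params, co$covariates)

  h1 <- res$tests[res$tests$hypothesis == "H1", ]
  expect_equal(nrow(h1), 18)
  expect_lt(abs(fisher_average(h1$estimate)$r_mean - 0.45), 0.12)
  h1a <- res$areas[res$areas$hypothesis == "H1", ]
  expect_true(any(h1a$significant & h1a$size == 18))

  # planted null: no significant sex effect on whitened peak amplitude
  h4p <- res$areas[res$areas$hypothesis == "H4_peak_amplitude", ]
  expect_true(nrow(h4p) == 0 || !any(h4p$significant))
  # but the planted sex effect on the slope-free intercept is found
  h4 <- res$areas[res$areas$hypothesis == "H4", ]
  expect_true(any(h4$significant))
  h5 <- res$areas[res$areas$hypothesis == "H5", ]
  expect_true(any(h5$significant))

  # H7: age-alpha association present in both IQ groups, no group difference
  expect_true(all(res$tests$p[res$tests$hypothesis == "H7_AIQ"] < 0.05))
  expect_gt(min(res$comparisons$p_difference), 0.05)

  expect_error(run_hypotheses(co$params, co$covariates[, c("subject_id", "sex")]),
               "age_years")
})

test_that("planted correlations are recovered within sampling error", {
  co <- synth_cohort(n_subjects = 170, seed = 41)
  df <- dplyr::inner_join(co$params, co$covariates, by = "subject_id")
  r_by_ch <- vapply(split(df, df$channel), function(d) {
    cor(d$age_years, d$alpha, use = "complete.obs")
  }, 0)
  expect_lt(abs(fisher_average(r_by_ch)$r_mean - 0.45), 0.12)
})
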