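test_that("exact contingency test matches the enumeration definition", {
  # symmetric 2x2
  expect_equal(as.numeric(fisher_exact(matrix(c(1, 0, 0, 1), 2))), 1)
  # degenerate margins
  p <- fisher_exact(matrix(c(0, 0, 3, 5), 2))
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "degenerate"))
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  # r x c enumeration against stats::fisher.test
  set.seed(11)
  for (i in 1:20) {
    m <- matrix(rpois(6, 4), nrow = 3)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(as.numeric(fisher_exact(m)), fisher.test(m)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("univariate screen tests, flags and forces retests correctly", {
  co <- impute_rf(generate_cohort(cohort_spec(seed = 5)), seed = 2)
  sc <- univariate_screen(co)
  expect_equal(nrow(sc), 53L)
  expect_setequal(unique(sc$test[sc$variable == "hba1c"]), "t")
  expect_setequal(unique(sc$test[sc$variable == "insulin"]), "fisher")
  # forced retests stay on even when non-significant
  faz_row <- sc[sc$variable == "faz_area_mm2", ]
  expect_true(faz_row$retest_requested)
  # a variable equal to the group label is flagged with p ~ 0
  co$mirror <- co$pnp_present
  sc2 <- univariate_screen(co)
  row <- sc2[sc2$variable == "mirror", ]
  expect_lt(row$p_value, 1e-10)
  expect_true(row$retest_requested)
  # constant variable skipped
  co$constv <- 1.0
  sc3 <- univariate_screen(co)
  expect_equal(sc3$test[sc3$variable == "constv"], "skipped")
})

test_that("random-forest imputation is deterministic and beats mean imputation", {
  co <- generate_cohort(cohort_spec(seed = 9, missingness = c()))
  expect_identical(impute_rf(co, seed = 1), co)   # complete table unchanged
  holed <- inject_missingness(co, c(hba1c = 1L, ldl = 2L), seed = 4)
  a <- impute_rf(holed, seed = 7)
  b <- impute_rf(holed, seed = 7)
  expect_identical(a, b)
  expect_false(any(is.na(a$hba1c)))
  # correlated multivariate normal: RF beats mean imputation most of the time
  wins <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 150
    z <- rnorm(n)
    dat <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                      v1 = z + rnorm(n, 0, 0.5),
                      v2 = z + rnorm(n, 0, 0.5),
                      v3 = z + rnorm(n, 0, 0.5))
    miss <- sample(n, 15)
    truth <- dat$v1[miss]
    holes <- dat; holes$v1[miss] <- NA
    imp <- impute_rf(holes, seed = s)
    rmse_rf <- sqrt(mean((imp$v1[miss] - truth)^2))
    rmse_mean <- sqrt(mean((mean(holes$v1, na.rm = TRUE) - truth)^2))
    if (rmse_rf < rmse_mean) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
  all_missing <- generate_cohort(cohort_spec(seed = 2, missingness = c()))
  all_missing$ldl <- NA_real_
  expect_error(impute_rf(all_missing, seed = 1), "entirely missing")
})

test_that("linear mixed model reduces to the two-sample comparison", {
  # one eye per patient: fixed effect equals the group mean difference
  set.seed(4)
  df <- data.frame(patient_id = sprintf("P%02d", 1:40),
                   pnp_present = rep(c("y", "n"), 20),
                   v = rnorm(40, 5, 1))
  f <- fit_lmm(df, "v", "none")
  diff_means <- mean(df$v[df$pnp_present == "y"]) -
    mean(df$v[df$pnp_present == "n"])
  expect_equal(abs(f$fixed_estimate), abs(diff_means), tolerance = 1e-6)
  expect_true(f$singular)
  # zero between-patient variance: matches ordinary regression
  set.seed(5)
  df2 <- data.frame(patient_id = rep(sprintf("P%02d", 1:30), each = 2),
                    pnp_present = sample(rep(c("y", "n"), 30)),
                    v = rnorm(60, 10, 2))
  f2 <- fit_lmm(df2, "v", "none")
  ols <- coef(lm(v ~ pnp_present, df2))[2]
  expect_lt(abs(abs(f2$fixed_estimate) - abs(ols)), 1e-3)
  # transformations are applied and labelled
  f3 <- fit_lmm(df2, "v", "sqrt")
  expect_equal(f3$transformation, "sqrt")
})

test_that("mixed logistic reduces to plain logistic when variance is zero", {
  set.seed(1)
  n <- 160   # 80 patients x 2 eyes, zero true between-patient variance
  df <- data.frame(patient_id = rep(sprintf("P%03d", 1:80), each = 2),
                   pnp_present = NA, x = rnorm(n))
  eta <- -0.3 + 1.2 * df$x
  df$resp <- ifelse(runif(n) < plogis(eta), "b", "a")
  df$pnp_present <- df$resp
  fm <- fit_logistic_mixed(df, "resp", fixed = "x", nagq = 15)
  gl <- glm(I(resp == "b") ~ x, df, family = binomial)
  expect_true(fm$singular)
  expect_lt(max(abs(fm$coefficients - coef(gl))), 1e-3)
  # quadrature convergence: 7 vs 25 nodes nearly identical log-likelihood
  df2 <- simulate_logistic_cohort(40, 2, betas = c(x1 = 1), random_sd = 1,
                                  seed = 3)
  f7 <- fit_logistic_mixed(df2, "pnp_present", fixed = "x1", nagq = 7)
  f25 <- fit_logistic_mixed(df2, "pnp_present", fixed = "x1", nagq = 25)
  expect_lt(abs(f7$loglik - f25$loglik), 1e-3)
  # complete separation is flagged
  sep <- data.frame(patient_id = sprintf("P%02d", 1:30),
                    pnp_present = rep(c("y", "n"), 15))
  sep$x <- ifelse(sep$pnp_present == "y", 1, 0)
  fs <- suppressWarnings(fit_logistic_mixed(sep, "pnp_present", fixed = "x"))
  expect_true(fs$separation)
})

test_that("multinomial mixed model: reduction, LRT calibration and drops", {
  # two categories: matches the binary mixed fit
  df <- simulate_logistic_cohort(40, 2, betas = c(x1 = 1.5), random_sd = 0.8,
                                 seed = 6)
  fb <- fit_multinomial_mixed(df, "pnp_present", fixed = "x1", nagq = 15)
  fg <- fit_logistic_mixed(df, "pnp_present", fixed = "x1", nagq = 15)
  expect_lt(abs(fb$beta - fg$coefficients[2]), 1e-3)
  # empty category dropped with a flag
  df$resp3 <- factor(sample(c("a", "b", "c"), nrow(df), replace = TRUE),
                     levels = c("a", "b", "c", "ghost"))
  fm <- fit_multinomial_mixed(df, "resp3")
  expect_equal(fm$dropped_categories, "ghost")
  expect_equal(length(fm$categories), 3L)
  expect_gte(fm$p_value, 0)
})

test_that("correlation pruning drops the redundant member and honours exclusions", {
  set.seed(12)
  n <- 60
  base <- rnorm(n)
  tab <- data.frame(patient_id = sprintf("P%02d", seq_len(n)),
                    a = base, b = base + rnorm(n, 0, 1e-6),
                    c = rnorm(n), prp = rnorm(n))
  out <- correlation_prune(tab, c("a", "b", "c", "prp"))
  expect_false("prp" %in% out$kept)
  expect_equal(out$dropped$reason[out$dropped$variable == "prp"], "manual")
  expect_equal(sum(out$kept %in% c("a", "b")), 1L)
  expect_true("c" %in% out$kept)
  expect_gte(max(out$dropped$r, na.rm = TRUE), 0.999)
  # constructed r ~ 0.95 pair: exactly one of the pair removed
  tab2 <- data.frame(patient_id = tab$patient_id,
                     p = base, q = 0.95 * base + sqrt(1 - 0.95^2) * rnorm(n),
                     ind = rnorm(n))
  out2 <- correlation_prune(tab2, c("p", "q", "ind"), r_threshold = 0.9)
  expect_equal(sum(out2$kept %in% c("p", "q")), 1L)
  expect_true("ind" %in% out2$kept)
})

test_that("backward-AIC selection: trivial cases and trace monotonicity", {
  sim <- simulate_logistic_cohort(60, 2, betas = c(x1 = 3), n_noise = 2,
                                  seed = 2)
  empty <- backward_aic_select(sim, character(0))
  expect_equal(empty$final_terms, character(0))
  expect_equal(nrow(empty$trace), 0L)
  sel <- backward_aic_select(sim, c("x1", "noise1", "noise2"))
  expect_true("x1" %in% sel$final_terms)
  # accepted deletions never increase AIC
  expect_true(all(diff(sel$trace$aic) <= 0))
  expect_true(all(sel$final_terms %in% sel$maximal_terms))
})

test_that("LOOCV AUC agrees with the concordance oracle and handles edge cases", {
  # scores identical to labels give AUC 1
  set.seed(21)
  lab <- rep(c(0, 1), 10)
  expect_equal(oracle_auc(lab, lab), 1)
  # pipeline AUC equals O(n^2) concordance counting on a 20-row fixture
  sim <- simulate_logistic_cohort(10, 2, betas = c(x1 = 2), random_sd = 0.5,
                                  seed = 14)
  lc <- loocv_auc(sim, "x1")
  ok <- !is.na(lc$scores)
  expect_equal(lc$auc, oracle_auc(lc$scores[ok], lc$labels[ok]),
               tolerance = 1e-12)
  expect_true(lc$ci[1] <= lc$auc && lc$auc <= lc$ci[2])
})

test_that("threshold stratification counts eyes exactly, boundary to reduced", {
  tab <- data.frame(
    patient_id = sprintf("P%02d", 1:8),
    pnp_present = c("y", "y", "n", "n", "y", "n", "y", "n"),
    perfusion_density = c(0.50, 0.44, 0.46, 0.45, 0.30, 0.52, NA, 0.41),
    faz_area_mm2 = c(0.2, 0.35, 0.25, 0.4, 0.31, 0.28, 0.33, NA))
  st <- stratify_thresholds(tab)
  # PD: 0.45 is NOT "normal" (strict >)
  expect_equal(as.numeric(st$pd["normal", "PNP"]), 1)     # 0.50
  expect_equal(as.numeric(st$pd["normal", "noPNP"]), 2)   # 0.46, 0.52
  expect_equal(as.numeric(st$pd["reduced", "PNP"]), 2)    # 0.44, 0.30
  expect_equal(as.numeric(st$pd["reduced", "noPNP"]), 2)  # 0.45, 0.41
  expect_equal(unname(st$excluded["pd"]), 1)
  expect_equal(as.numeric(st$faz["preserved", "PNP"]), 1) # 0.2
  expect_equal(unname(st$excluded["faz"]), 1)
  # degenerate: all one cell
  tab2 <- data.frame(patient_id = "P01", pnp_present = rep("n", 5),
                     perfusion_density = rep(0.5, 5),
                     faz_area_mm2 = rep(0.2, 5))
  st2 <- stratify_thresholds(tab2)
  expect_equal(as.numeric(st2$pd["normal", "noPNP"]), 5)
  expect_equal(sum(st2$pd), 5)
})
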