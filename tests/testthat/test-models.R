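two_by_two <- function(a, b, c, d) {
  data.frame(y = rep(c(1, 1, 0, 0), c(a, b, c, d)),
             x = rep(c(1, 0, 1, 0), c(a, b, c, d)))
}

test_that("univariate screen applies the right test per variable type", {
  d <- two_by_two(20, 10, 10, 20)
  d$sexlike <- ifelse(d$x == 1, "Male", "Female")
  d$flat <- 1
  rep_ <- univariate_tests(d, outcome = "y", continuous = c("x", "flat"),
                           categorical = "sexlike")
  chi <- rep_[rep_$variable == "sexlike", ]
  expect_equal(chi$statistic, 20 / 3, tolerance = 1e-6)
  expect_match(rep_[rep_$variable == "flat", "note"], "skipped")

  # identical value sequences in both outcome groups => t statistic 0
  d$equal <- ave(seq_len(nrow(d)), d$y, FUN = seq_along)
  req <- univariate_tests(d, outcome = "y", continuous = "equal")
  expect_lt(abs(req$statistic), 1e-10)
})

test_that("null univariate p-values are approximately uniform", {
  set.seed(41)
  ps <- replicate(400, {
    y <- rbinom(60, 1, 0.5)
    x <- rnorm(60)
    t.test(x[y == 1], x[y == 0], var.equal = TRUE)$p.value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  ours <- replicate(100, {
    d <- data.frame(participated = rbinom(60, 1, 0.5), v = rnorm(60))
    univariate_tests(d, continuous = "v")$p_value
  })
  expect_true(mean(ours < 0.05) < 0.12)
})

test_that("missing age is counted per group but excluded from the t-test", {
  set.seed(42)
  d <- data.frame(participated = rbinom(80, 1, 0.5), age = rnorm(80, 42, 8))
  d$age[1:10] <- NA
  rep_ <- univariate_tests(d, continuous = "age")
  expect_equal(rep_$missing_participated + rep_$missing_not, 10)
  with_na <- d$age[!is.na(d$age)]
  grp <- d$participated[!is.na(d$age)]
  expect_equal(rep_$statistic,
               unname(t.test(with_na[grp == 1], with_na[grp == 0],
                             var.equal = TRUE)$statistic))
})

test_that("the saturated 2x2 logistic fit reproduces the closed-form odds ratio", {
  d <- two_by_two(20, 10, 10, 20)
  f <- fit_participation(model_spec("x", outcome = "y"), d)
  expect_equal(f$coefficients$or[f$coefficients$term == "x"], 4,
               tolerance = 1e-6)
  # OR/CI consistency: exponentiated coefficient CI endpoints
  ct <- f$coefficients
  expect_equal(ct$ci_low, exp(ct$estimate - qnorm(0.975) * ct$se),
               tolerance = 1e-12)
  expect_equal(ct$ci_high, exp(ct$estimate + qnorm(0.975) * ct$se),
               tolerance = 1e-12)
  expect_equal(ct$or, exp(ct$estimate), tolerance = 1e-12)

  d$x2 <- d$x
  expect_error(fit_participation(model_spec(c("x", "x2"), outcome = "y"), d),
               "collinear")
})

test_that("age enters only as the missingness-safe pair", {
  sp <- model_spec(c("age", "years_c"))
  expect_true(all(c("age_c_obs", "age_observed") %in% sp$terms))
  expect_false("age" %in% sp$terms)
  expect_error(model_spec("age:wy_wi"), "pair")
})

test_that("Wald intervals have near-nominal null coverage and type-I error", {
  set.seed(43)
  n_rep <- 250
  cover1 <- logical(n_rep)
  reject <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    d <- data.frame(y = rbinom(1000, 1, 0.5), x = rnorm(1000))
    f <- fit_participation(model_spec("x", outcome = "y"), d)
    ct <- f$coefficients[f$coefficients$term == "x", ]
    cover1[r] <- ct$ci_low <= 1 && ct$ci_high >= 1
    reject[r] <- ct$p_value < 0.05
  }
  expect_gte(mean(cover1), 0.91)
  expect_lte(mean(cover1), 0.985)
  expect_gte(mean(reject), 0.015)
  expect_lte(mean(reject), 0.09)
})

test_that("random-intercept fits report tau and degenerate groupings error", {
  set.seed(44)
  g <- rep(1:25, each = 20)
  theta <- rnorm(25, 0, 1)
  d <- data.frame(y = rbinom(500, 1, plogis(theta[g])),
                  g = paste0("h", g))
  f <- fit_participation(model_spec(character(0), outcome = "y",
                                    random_intercept = "g"), d)
  expect_gt(f$tau, 0.3)
  expect_equal(f$engine, "glmer")

  d1 <- d[d$g == "h1", ]
  expect_error(fit_participation(model_spec(character(0), outcome = "y",
                                            random_intercept = "g"), d1),
               "fixed-effect")
})

test_that("tau = 0 random-intercept fits match the plain logistic fit", {
  set.seed(45)
  d <- data.frame(x = rnorm(800), g = paste0("h", rep(1:40, each = 20)))
  d$y <- rbinom(800, 1, plogis(0.4 * d$x))
  fr <- fit_participation(model_spec("x", outcome = "y",
                                     random_intercept = "g"), d)
  ff <- fit_participation(model_spec("x", outcome = "y"), d)
  expect_lt(abs(fr$coefficients$estimate[2] - ff$coefficients$estimate[2]),
            0.05)
  expect_lt(fr$tau, 0.25)
})

test_that("backward reduction drops the weakest term and respects marginality", {
  set.seed(46)
  n <- 1200
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), noise = rnorm(n))
  d$participated <- rbinom(n, 1, plogis(0.8 * d$x1 + 0.7 * d$x2 +
                                          0.6 * d$x1 * d$x2))
  red <- reduce_model(model_spec(c("x1", "x2", "noise", "x1:x2")), d)
  expect_setequal(red$spec$terms, c("x1", "x2", "x1:x2"))
  expect_equal(red$trace$unit, "noise")
  expect_equal(nrow(red$trace), 1)

  # all-significant model is unchanged, with an empty trace
  red2 <- reduce_model(model_spec(c("x1", "x2")), d)
  expect_setequal(red2$spec$terms, c("x1", "x2"))
  expect_equal(nrow(red2$trace), 0)

  # age pair is dropped together when centered age is uninformative
  set.seed(47)
  d2 <- data.frame(age = rnorm(800, 42, 8), sex = "Male",
                   years_org = rnorm(800, 3.6, 0.8))
  d2$age[sample.int(800, 120)] <- NA
  d2$age_observed <- as.integer(!is.na(d2$age))
  covs <- derive_covariates(d2)
  d2 <- cbind(d2, covs)
  d2$participated <- rbinom(800, 1, plogis(0.9 * covs$years_c))
  red3 <- reduce_model(model_spec(c("age", "years_c")), d2)
  expect_false(any(c("age_c_obs", "age_observed") %in% red3$spec$terms))
  expect_true("years_c" %in% red3$spec$terms)
  expect_equal(nrow(red3$trace), 1)  # the pair leaves as one unit
})

test_that("pure-noise models reduce to (near) empty most of the time", {
  set.seed(48)
  empties <- replicate(15, {
    d <- data.frame(a = rnorm(700), b = rnorm(700), c = rnorm(700))
    d$participated <- rbinom(700, 1, 0.5)
    length(reduce_model(model_spec(c("a", "b", "c")), d)$spec$terms)
  })
  expect_gte(mean(empties == 0), 0.6)
})

test_that("small parameter-recovery runs are seed-stable and well calibrated", {
  cfg <- small_config(seed = 1, tau = 0)
  r1 <- parameter_recovery(cfg, n_reps = 8, seed = 5)
  r2 <- parameter_recovery(cfg, n_reps = 8, seed = 5)
  expect_identical(attr(r1, "estimates"), attr(r2, "estimates"))
  expect_true(all(c("(Intercept)", "years_c", "H", "wy_wi", "wy_ac_trans")
                  %in% r1$coefficient))
  expect_false(anyNA(r1$mean_est))
  # the typical replicate recovers the within-exposure effect tightly even
  # at this small size (the median is robust to the occasional unstable
  # small-study fit; the mean is exercised at realistic sizes elsewhere)
  est_wi <- attr(r1, "estimates")[, "wy_wi"]
  expect_lt(abs(median(est_wi, na.rm = TRUE) -
                  r1$truth[r1$coefficient == "wy_wi"]), 0.03)
})

test_that("a strong diversity effect has its sign recovered", {
  beta <- list(b0 = -1, b1 = c(years_c = 0), b2 = 3, b3 = 0, b4 = 0, b5 = 0)
  cfg <- sim_config(n_hospitals = 15L, physicians_per_hospital = 20L,
                    patients_per_hospital = c(15L, 25L),
                    beta = beta, tau = 0, seed = 3)
  r <- parameter_recovery(cfg, n_reps = 12, seed = 9)
  est <- attr(r, "estimates")[, "H"]
  expect_gte(mean(est > 0), 0.95)
})
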