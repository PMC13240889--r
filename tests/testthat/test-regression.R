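two_group_data <- function(n_per = 6) {
  tibble::tibble(
    cluster = rep(c("mainly ST", "mainly NW"), each = n_per),
    y = c(rnorm(n_per, 50, 1), rnorm(n_per, 46, 1)),
    z = rnorm(2 * n_per)
  )
}

test_that("noiseless linear fit is exact", {
  d <- tibble::tibble(cluster = rep(c("a", "b"), each = 5),
                      x = rep(c(0, 1), each = 5))
  d$y <- 3 + 2 * d$x
  spec <- model_spec("y", "linear", exposure = "cluster", reference = "a",
                     standardized = FALSE)
  # suppress base R's "essentially perfect fit" note on the zero-residual fit
  fit <- suppressWarnings(fit_linear(spec, d))
  expect_equal(unname(coef(fit$model)), c(3, 2), tolerance = 1e-12)
})

test_that("linear estimates equal the normal-equations oracle", {
  set.seed(12)
  d <- tibble::tibble(
    cluster = sample(c("mainly ST", "mainly NW", "volatile"), 20,
                     replace = TRUE),
    z = rnorm(20), w = runif(20))
  d$y <- 50 - 4 * (d$cluster == "mainly NW") - 2 * (d$cluster == "volatile") +
    0.5 * d$z + rnorm(20)
  spec <- model_spec("y", "linear", reference = "mainly ST",
                     covariates = c("z", "w"))
  fit <- fit_linear(spec, d)
  X <- cbind(1, d$cluster == "mainly NW", d$cluster == "volatile", d$z, d$w)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(unname(coef(fit$model)), as.numeric(beta), tolerance = 1e-6)
  # effect table carries SD-unit effect sizes (estimate / 10)
  tbl <- tidy(fit)
  expect_equal(tbl$effect_size_sd, tbl$estimate / 10)
  expect_equal(tbl$n, rep(20, nrow(tbl)))
})

test_that("an exactly orthogonal covariate leaves the exposure estimate unchanged", {
  set.seed(8)
  d <- tibble::tibble(cluster = rep(c("ref", "exp"), each = 10))
  d$y <- 50 - 3 * (d$cluster == "exp") + rnorm(20)
  # centered within each exposure group -> exactly orthogonal to the dummy
  d$z <- c(scale(rnorm(10), scale = FALSE), scale(rnorm(10), scale = FALSE))
  f0 <- fit_linear(model_spec("y", "linear", reference = "ref",
                              standardized = FALSE), d)
  f1 <- fit_linear(model_spec("y", "linear", reference = "ref",
                              covariates = "z", standardized = FALSE), d)
  e0 <- tidy(f0)$estimate[grepl("exp", tidy(f0)$term)]
  e1 <- tidy(f1)$estimate[grepl("exp", tidy(f1)$term)]
  expect_equal(e0, e1, tolerance = 1e-9)
})

test_that("rank deficiency is reported with the collinear term", {
  d <- two_group_data()
  d$dup <- as.numeric(d$cluster == "mainly NW")
  spec <- model_spec("y", "linear", reference = "mainly ST",
                     covariates = "dup", standardized = FALSE)
  expect_error(fit_linear(spec, d), "collinear")
})

test_that("logistic 2x2 recovers the closed-form log odds ratio", {
  d <- tibble::tibble(
    cluster = c(rep("exposed", 100), rep("ref", 100)),
    y = c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90)))
  spec <- model_spec("y", "logistic", reference = "ref")
  fit <- fit_logistic(spec, d)
  est <- tidy(fit)$estimate[grepl("exposed", tidy(fit)$term)]
  expect_equal(est, log(2.25), tolerance = 1e-6)
  # intercept is the reference-group log odds
  expect_equal(tidy(fit)$estimate[1], log(10 / 90), tolerance = 1e-6)
})

test_that("degenerate and separated logistic outcomes raise errors", {
  d <- two_group_data()
  d$y <- 0
  expect_error(fit_logistic(model_spec("y", "logistic",
                                       reference = "mainly ST"), d),
               "degenerate")
  d2 <- tibble::tibble(cluster = rep(c("a", "b"), each = 10),
                       y = rep(c(0, 1), each = 10))
  expect_error(fit_logistic(model_spec("y", "logistic", reference = "a"), d2),
               "separation")
})

test_that("logistic fit is a local maximum of the likelihood", {
  set.seed(9)
  d <- tibble::tibble(cluster = sample(c("a", "b"), 50, replace = TRUE),
                      z = rnorm(50))
  d$y <- rbinom(50, 1, plogis(-0.3 + 0.8 * (d$cluster == "b") + 0.5 * d$z))
  fit <- fit_logistic(model_spec("y", "logistic", reference = "a",
                                 covariates = "z"), d)
  X <- cbind(1, d$cluster == "b", d$z)
  loglik <- function(beta) {
    eta <- as.numeric(X %*% beta)
    sum(d$y * eta - log1p(exp(eta)))
  }
  b_hat <- unname(coef(fit$model))
  ll_hat <- loglik(b_hat)
  set.seed(10)
  for (i in 1:20) {
    expect_gte(ll_hat, loglik(b_hat + rnorm(3, 0, 0.05)))
  }
})

test_that("switching the reference changes contrasts but not fitted values", {
  set.seed(14)
  d <- tibble::tibble(
    cluster = sample(c("mainly ST", "mainly NW", "volatile"), 60,
                     replace = TRUE),
    z = rnorm(60))
  d$y <- 50 - 4 * (d$cluster == "mainly NW") + d$z + rnorm(60)
  f1 <- fit_linear(model_spec("y", "linear", reference = "mainly ST",
                              covariates = "z", standardized = FALSE), d)
  f2 <- fit_linear(model_spec("y", "linear", reference = "volatile",
                              covariates = "z", standardized = FALSE), d)
  expect_lt(max(abs(fitted(f1$model) - fitted(f2$model))), 1e-9)
})

test_that("gender interaction model reports and counts product terms", {
  set.seed(15)
  n <- 400
  d <- tibble::tibble(
    cluster = sample(c("mainly ST", "mainly NW", "volatile"), n,
                     replace = TRUE),
    female = rbinom(n, 1, 0.5))
  d$y <- 50 - 3 * (d$cluster == "mainly NW") + rnorm(n, 0, 10)
  spec <- model_spec("y", "linear", reference = "mainly ST",
                     interaction = "female")
  fit <- fit_gender_interaction(spec, d)
  expect_equal(fit$n_interactions, 2L)
  expect_true(all(grepl(":", fit$interaction_terms)))
  expect_match(fit$note, "interaction terms")
  # constant interaction factor is a configuration error
  d$female <- 1
  expect_error(fit_gender_interaction(spec, d), "constant")
  # spec without interaction factor is rejected
  expect_error(fit_gender_interaction(model_spec("y", "linear",
                                                 reference = "mainly ST"), d),
               "no interaction")
})

test_that("null interactions are significant at roughly the nominal 5% rate", {
  set.seed(16)
  n_sig <- 0L; n_terms <- 0L
  for (rep in 1:40) {
    n <- 300
    d <- tibble::tibble(
      cluster = sample(c("a", "b", "c"), n, replace = TRUE),
      female = rbinom(n, 1, 0.5))
    d$y <- 50 - 2 * (d$cluster == "b") + rnorm(n, 0, 10)
    fit <- fit_gender_interaction(
      model_spec("y", "linear", reference = "a", interaction = "female"), d)
    n_sig <- n_sig + fit$n_significant
    n_terms <- n_terms + fit$n_interactions
  }
  # 80 null terms at alpha = .05: expect ~4 significant; allow wide band
  expect_gte(n_terms, 80L)
  expect_lte(n_sig, 12L)
})

test_that("an injected cluster-by-gender effect is detected with high power", {
  # a 5-point interaction at n = 2000 under SD-10 noise has ~98% power for
  # the mainly-NW x female Wald test (SE ~ 1.2 given the class shares)
  hits <- 0L
  for (seed in 1:5) {
    om <- default_outcome_model()
    om$interaction_female["mainly_NW"] <- 5
    sim <- generate_panel(generator_config(n_persons = 2000,
                                           outcome_model = om, seed = seed))
    dat <- dplyr::inner_join(sim$truth, sim$covariates, by = "person_id") |>
      dplyr::inner_join(sim$outcomes, by = "person_id")
    fit <- fit_gender_interaction(
      model_spec("sf_physical", "linear", exposure = "class_name",
                 reference = "mainly_ST",
                 covariates = c("education", "partnered"),
                 interaction = "female"), dat)
    tbl <- tidy(fit)
    row <- tbl[grepl("mainly_NW", tbl$term) & grepl(":", tbl$term), ]
    if (nrow(row) == 1 && row$p.value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("effect-size report renders the significant-cells convention", {
  tbl <- tibble::tibble(
    term = c("(Intercept)", "clusterNW", "clusterVol", "clusterX"),
    estimate = c(50, -4.0, 0.4, 2.0),
    std.error = 1, statistic = 0,
    p.value = c(0, 0.001, 0.6, 0.01), n = 100,
    effect_size_sd = c(5, -0.4, 0.04, 0.2))
  rep <- effect_size_report(tbl, family = "linear")
  expect_equal(rep$cell, c("", "-4", "", "+2"))
  # logistic symbols
  tbl2 <- tibble::tibble(term = c("(Intercept)", "clusterNW", "clusterVol"),
                         estimate = c(-2, 0.8, -0.5), std.error = 1,
                         statistic = 0, p.value = c(0, 0.01, 0.3), n = 100)
  expect_equal(effect_size_report(tbl2, family = "logistic")$cell,
               c("", "+", ""))
})
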