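test_that("generation is deterministic given config and seed", {
  cfg <- generator_config(n_persons = 60, seed = 42)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a$panel, b$panel)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$truth, b$truth)
  d <- generate_panel(cfg, seed = 43)
  expect_false(identical(a$panel, d$panel))
})

test_that("degenerate chain: one always-ST class with full spans gives ten ST states", {
  cls <- list(all_ST = list(
    init = c(NW = 0, ST = 1, EVE = 0, NGT = 0, ONS = 0),
    kernel = default_class_profiles()$mainly_ST$kernel,
    home = "ST", volatility = 0))
  cfg <- generator_config(n_persons = 25, class_weights = c(all_ST = 1),
                          classes = cls, obs_span_dist = c(`10` = 1),
                          seed = 3)
  sim <- generate_panel(cfg)
  obs <- sim$panel[sim$panel$observed, ]
  expect_true(all(obs$state == "ST"))
  expect_equal(nrow(obs), 25 * 10)
})

test_that("noiseless limit: outcome equals 50 + own class effect exactly", {
  om <- default_outcome_model()
  om$resid_sd <- 0
  om$beta_female <- 0; om$beta_edu_mid <- 0; om$beta_edu_high <- 0
  om$beta_partnered <- 0
  cfg <- generator_config(n_persons = 120, outcome_model = om, seed = 9)
  sim <- generate_panel(cfg)
  expected <- 50 + sim$truth$injected_effect
  expect_equal(sim$outcomes$sf_physical, expected, tolerance = 1e-12)
})

test_that("empirical class shares track the configured weights at n = 2000", {
  cfg <- generator_config(n_persons = 2000, seed = 1)
  sim <- generate_panel(cfg)
  shares <- as.numeric(table(factor(sim$truth$class_name,
                                    levels = names(cfg$class_weights)))) / 2000
  expect_true(all(abs(shares - unname(cfg$class_weights)) <= 0.03))
})

test_that("every person satisfies the 7-consecutive-years rule by construction", {
  sim <- generate_panel(generator_config(n_persons = 150, seed = 5))
  spans <- sim$truth$span_last - sim$truth$span_first + 1
  expect_true(all(spans >= 7 & spans <= 10))
  seqs <- encode_sequences(sim$panel, c(25, 34))
  expect_equal(nrow(eligibility_filter(seqs, 7)), nrow(seqs))
})

test_that("mean state changes are monotone in volatility and vanish at 0", {
  base <- default_class_profiles()$mainly_ST
  mean_switches <- function(v) {
    cls <- list(c1 = utils::modifyList(base, list(volatility = v)))
    cfg <- generator_config(n_persons = 250, class_weights = c(c1 = 1),
                            classes = cls, obs_span_dist = c(`10` = 1),
                            seed = 11)
    sim <- generate_panel(cfg)
    st <- matrix(sim$panel$state, ncol = 10, byrow = TRUE)
    mean(rowSums(st[, -1] != st[, -10]))
  }
  ms <- vapply(c(0, 1, 3, 6), mean_switches, numeric(1))
  # at volatility 0 the only switches are reversions of the ~5% of persons
  # whose initial draw is an excursion state
  expect_lt(ms[1], 0.2)
  expect_true(all(diff(ms) > 0.3))
})

test_that("invalid configurations name the offending field", {
  expect_error(generator_config(class_weights = c(a = 0.5, b = 0.6)),
               "class_weights")
  expect_error(generator_config(obs_span_dist = c(`5` = 1)), "obs_span_dist")
  cls <- default_class_profiles()
  cls$mainly_ST$kernel[2, 2] <- 0.5
  expect_error(generator_config(classes = cls), "kernel")
})

test_that("OLS on true class labels recovers injected effects within 1.5 points", {
  hits <- 0L
  for (seed in 1:5) {
    sim <- generate_panel(generator_config(n_persons = 2000, seed = seed))
    dat <- dplyr::inner_join(sim$truth, sim$covariates, by = "person_id") |>
      dplyr::inner_join(sim$outcomes, by = "person_id")
    dat$class_name <- stats::relevel(factor(dat$class_name),
                                     ref = "mainly_ST")
    fit <- lm(sf_physical ~ class_name + female + education + partnered,
              data = dat)
    est <- coef(fit)[paste0("class_name",
                            c("mainly_NW", "mainly_NST", "volatile"))]
    truth <- c(-4, -2, -3)
    if (all(abs(est - truth) <= 1.5)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("adjusted Rand index matches hand-computed and reference values", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  # relabeling invariance
  expect_equal(adjusted_rand_index(c(1, 2, 1, 3), c(3, 1, 3, 2)), 1)
  # all singletons vs one cluster on n = 4: sum_ij = 0, expected = 0,
  # max index = (0 + 6) / 2 = 3, so ARI = 0
  expect_equal(adjusted_rand_index(1:4, rep(1, 4)), 0)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
  skip_if_not_installed("mclust")
  set.seed(7)
  for (i in 1:10) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("item nonresponse appears inside spans at the configured rate", {
  cfg <- generator_config(n_persons = 400, mis_rate = 0.1, seed = 2)
  sim <- generate_panel(cfg)
  pos <- sim$panel$age - 24
  first <- sim$truth$span_first[match(sim$panel$person_id,
                                      sim$truth$person_id)]
  last <- sim$truth$span_last[match(sim$panel$person_id,
                                    sim$truth$person_id)]
  inside <- pos >= first & pos <= last
  rate <- mean(!sim$panel$observed[inside])
  expect_gt(rate, 0.06)
  expect_lt(rate, 0.14)
})
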