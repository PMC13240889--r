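#' Configuration for the synthetic panel generator
#'
#' Builds (and validates) the full parameter set for [generate_panel()]. The
#' defaults emulate the structure of the restricted household panels the
#' pipeline is designed for: a 10-year age window, five work-schedule states
#' plus missingness, 7-10 consecutive observed years per person (most people
#' observed 7-8 years, so trailing missingness is common), latent trajectory
#' classes with archetypal profiles, and health outcomes at the window-end
#' age generated on the standardized scale (mean 50, SD 10) with additive
#' class effects in points.
#'
#' Four archetype classes are shipped as defaults: `mainly_NW`, `mainly_ST`
#' (the largest class and the downstream reference), `mainly_NST`
#' (nonstandard work concentrated on the other-nonstandard state), and
#' `volatile` (frequent oscillation between daytime and nonstandard work).
#' Each class is a list with an initial-state distribution over the five
#' working states, a switch kernel `K` (given that a switch happens, where it
#' goes), a `home` state set, and a volatility `v`: the expected number of
#' switches out of home per decade. See [class_transition_matrix()] for how
#' these combine into the per-year Markov matrix; excursions away from home
#' revert quickly, so classes stay coherent in sequence space while
#' volatility 0 freezes trajectories at their initial state.
#'
#' @param n_persons Number of persons to generate.
#' @param window_start First age of the 10-year window (default 25, i.e.
#'   ages 25-34 with outcomes at 35).
#' @param class_weights Named probability vector over classes; must sum to 1.
#' @param classes Named list of class profiles (`init`, `kernel`,
#'   `volatility`); see Details. Defaults to the four archetypes.
#' @param obs_span_dist Named probability vector over consecutive observed
#'   span lengths; support must lie in 7..10.
#' @param mis_rate Probability that an inside-span year is item-missing
#'   (interviewed but schedule not reported). Default 0.
#' @param cov_missing_rate Probability that a person's education covariate is
#'   missing (for exercising the complete-case filter). Default 0.
#' @param outcome_model List with `intercept` (default 50), `resid_sd`
#'   (default 10), per-class point effects `sf_physical` and `sf_mental`
#'   (reference class 0), covariate coefficients `beta_female`, `beta_edu_mid`,
#'   `beta_edu_high`, `beta_partnered`, an optional `interaction_female`
#'   vector of extra per-class effects for women, per-class log-odds
#'   `poor_fair_logit` with `poor_fair_intercept`, and distress parameters
#'   `distress_base`, `distress_effects`, `distress_sd`, `instrument`.
#' @param seed Integer seed stored with the config; [generate_panel()] uses
#'   it unless overridden.
#' @return A validated list of class `ws_generator_config`.
#' @export
generator_config <- function(n_persons = 500,
                             window_start = 25,
                             class_weights = c(mainly_NW = 0.20,
                                               mainly_ST = 0.45,
                                               mainly_NST = 0.15,
                                               volatile = 0.20),
                             classes = default_class_profiles(),
                             obs_span_dist = c(`7` = 0.35, `8` = 0.30,
                                               `9` = 0.15, `10` = 0.20),
                             mis_rate = 0,
                             cov_missing_rate = 0,
                             outcome_model = default_outcome_model(),
                             seed = 1L) {
  cfg <- list(
    n_persons = n_persons, window_start = window_start,
    class_weights = class_weights, classes = classes,
    obs_span_dist = obs_span_dist, mis_rate = mis_rate,
    cov_missing_rate = cov_missing_rate,
    outcome_model = utils::modifyList(default_outcome_model(), outcome_model),
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "ws_generator_config")
}

#' @rdname generator_config
#' @export
default_class_profiles <- function() {
  st <- .WS_WORK_STATES
  kernel <- function(rows) {
    k <- do.call(rbind, rows)
    dimnames(k) <- list(st, st)
    k
  }
  list(
    mainly_NW = list(
      init = c(NW = .95, ST = .03, EVE = .01, NGT = .005, ONS = .005),
      kernel = kernel(list(
        c(0, .70, .10, .10, .10),   # from NW: re-entry mostly to daytime work
        c(.90, 0, .04, .03, .03),   # excursions revert to NW quickly
        c(.85, .05, 0, .05, .05),
        c(.85, .05, .05, 0, .05),
        c(.85, .05, .05, .05, 0))),
      home = "NW", volatility = 0.5, return_rate = 0.8),
    mainly_ST = list(
      init = c(NW = .02, ST = .95, EVE = .015, NGT = .0075, ONS = .0075),
      kernel = kernel(list(
        c(0, .90, .04, .03, .03),
        c(.40, 0, .20, .20, .20),
        c(.05, .85, 0, .05, .05),
        c(.05, .85, .05, 0, .05),
        c(.05, .85, .05, .05, 0))),
      home = "ST", volatility = 0.5, return_rate = 0.8),
    mainly_NST = list(
      init = c(NW = .01, ST = .02, EVE = .02, NGT = .10, ONS = .85),
      kernel = kernel(list(
        c(0, .05, .10, .25, .60),
        c(.02, 0, .10, .28, .60),
        c(.02, .08, 0, .30, .60),   # nonstandard work stays in the NST block
        c(.02, .08, .10, 0, .80),
        c(.02, .08, .10, .80, 0))),
      home = c("NGT", "ONS"), volatility = 0.6, return_rate = 0.8),
    volatile = list(
      init = c(NW = .20, ST = .20, EVE = .20, NGT = .20, ONS = .20),
      kernel = kernel(list(
        c(0, .25, .25, .25, .25),
        c(.25, 0, .25, .25, .25),   # churns across all schedules
        c(.25, .25, 0, .25, .25),
        c(.25, .25, .25, 0, .25),
        c(.25, .25, .25, .25, 0))),
      home = .WS_WORK_STATES, volatility = 5)
  )
}

#' @rdname generator_config
#' @export
default_outcome_model <- function() {
  list(
    intercept = 50, resid_sd = 10,
    sf_physical = c(mainly_NW = -4, mainly_ST = 0, mainly_NST = -2,
                    volatile = -3),
    sf_mental = c(mainly_NW = -3, mainly_ST = 0, mainly_NST = -1.5,
                  volatile = -2.5),
    beta_female = -0.5, beta_edu_mid = 0.5, beta_edu_high = 1.0,
    beta_partnered = 0.3,
    interaction_female = c(mainly_NW = 0, mainly_ST = 0, mainly_NST = 0,
                           volatile = 0),
    poor_fair_intercept = qlogis(0.12),
    poor_fair_logit = c(mainly_NW = 0.8, mainly_ST = 0, mainly_NST = 0.4,
                        volatile = 0.6),
    distress_base = 14, distress_sd = 5, instrument = "K10",
    distress_effects = c(mainly_NW = 3, mainly_ST = 0, mainly_NST = 1.5,
                         volatile = 2.5)
  )
}

validate_generator_config <- function(cfg) {
  stop_cfg <- function(field, msg) {
    stop("invalid generator configuration [", field, "]: ", msg, call. = FALSE)
  }
  if (!is.numeric(cfg$n_persons) || cfg$n_persons < 1) {
    stop_cfg("n_persons", "must be a positive count")
  }
  w <- cfg$class_weights
  if (any(w < 0) || abs(sum(w) - 1) > 1e-12) {
    stop_cfg("class_weights", "must be nonnegative and sum to 1")
  }
  if (!setequal(names(w), names(cfg$classes))) {
    stop_cfg("class_weights", "names must match the class profiles")
  }
  sp <- cfg$obs_span_dist
  if (!all(names(sp) %in% as.character(7:10))) {
    stop_cfg("obs_span_dist", "support must be within {7, 8, 9, 10}")
  }
  if (any(sp < 0) || abs(sum(sp) - 1) > 1e-12) {
    stop_cfg("obs_span_dist", "must be a probability vector summing to 1")
  }
  for (nm in names(cfg$classes)) {
    cl <- cfg$classes[[nm]]
    if (any(cl$init < 0) || abs(sum(cl$init) - 1) > 1e-12) {
      stop_cfg(paste0("classes$", nm, "$init"),
               "initial-state distribution must sum to 1")
    }
    k <- cl$kernel
    if (any(diag(k) != 0)) {
      stop_cfg(paste0("classes$", nm, "$kernel"), "diagonal must be zero")
    }
    if (any(k < 0) || any(abs(rowSums(k) - 1) > 1e-12)) {
      stop_cfg(paste0("classes$", nm, "$kernel"), "rows must sum to 1")
    }
    if (cl$volatility < 0 || cl$volatility > 9) {
      stop_cfg(paste0("classes$", nm, "$volatility"),
               "expected switches per decade must lie in [0, 9]")
    }
    if (is.null(cl$home) || !all(cl$home %in% .WS_WORK_STATES)) {
      stop_cfg(paste0("classes$", nm, "$home"),
               "home must be a subset of the working states")
    }
  }
  m <- cfg$outcome_model
  if (!is.numeric(m$resid_sd) || m$resid_sd < 0) {
    stop_cfg("outcome_model$resid_sd", "must be nonnegative")
  }
  invisible(cfg)
}

#' Per-year Markov transition matrix for a class profile
#'
#' Rows for the class's `home` states mix identity and switch kernel as
#' `(1 - v/9) * e_a + (v/9) * K[a, ]`, so the volatility `v` is the expected
#' number of switches out of home per decade (9 year-to-year moves) while the
#' chain sits at home. Rows for non-home states use a fixed `return_rate`
#' instead (default 0.6), so excursions are short and mean-reverting: with
#' `v -> 0` a person starting at home never leaves, giving the class-profile
#' minimum number of switches, and the expected switch count is monotone
#' in `v`.
#'
#' @param profile A class profile from a [generator_config()] (fields
#'   `init`, `kernel`, `home`, `volatility`, optional `return_rate`).
#' @return A 5x5 row-stochastic matrix over the working states.
#' @export
class_transition_matrix <- function(profile) {
  v_out <- profile$volatility / 9
  ret <- if (is.null(profile$return_rate)) 0.6 else profile$return_rate
  m <- matrix(0, 5, 5, dimnames = list(.WS_WORK_STATES, .WS_WORK_STATES))
  for (a in seq_len(5)) {
    out <- if (.WS_WORK_STATES[a] %in% profile$home) v_out else ret
    m[a, ] <- out * profile$kernel[a, ]
    m[a, a] <- m[a, a] + (1 - out)
  }
  m
}

#' Generate a synthetic person-year panel with known trajectory classes
#'
#' Draws a latent class per person, simulates the work-schedule Markov chain
#' over the 10-year window, places one contiguous observed span (7-10 years)
#' uniformly within the window, and generates covariates and window-end
#' health outcomes with the configured injected class effects. Everything is
#' driven by a single seeded RNG stream; identical config + seed gives a
#' bit-identical result.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list of class `ws_sim` with tibbles `panel` (person_id, age,
#'   state, weekly_hours, occupation, observed), `covariates`, `outcomes`,
#'   and `truth` (person_id, latent_class, class_name, injected_effect,
#'   span_first, span_last).
#' @examples
#' sim <- generate_panel(generator_config(n_persons = 50, seed = 42))
#' dplyr::count(sim$truth, class_name)
#' @export
generate_panel <- function(config = generator_config(), seed = config$seed) {
  validate_generator_config(config)
  withr::with_seed(as.integer(seed), generate_panel_impl(config))
}

generate_panel_impl <- function(cfg) {
  n <- cfg$n_persons
  class_names <- names(cfg$class_weights)
  trans <- lapply(cfg$classes, class_transition_matrix)
  ages <- cfg$window_start + 0:9

  latent <- sample(seq_along(class_names), n, replace = TRUE,
                   prob = cfg$class_weights)
  span_len <- as.integer(sample(names(cfg$obs_span_dist), n, replace = TRUE,
                                prob = cfg$obs_span_dist))
  span_first <- vapply(span_len, function(len) {
    sample.int(10L - len + 1L, 1L)
  }, integer(1))
  span_last <- span_first + span_len - 1L

  # covariates
  female <- rbinom(n, 1, 0.5)
  edu_probs <- list(mainly_NW = c(.45, .40, .15), mainly_ST = c(.25, .45, .30),
                    mainly_NST = c(.40, .40, .20), volatile = c(.35, .40, .25))
  education <- vapply(latent, function(cl) {
    p <- edu_probs[[class_names[cl]]]
    if (is.null(p)) p <- c(1, 1, 1) / 3
    sample(c("low", "mid", "high"), 1, prob = p)
  }, character(1))
  partnered <- rbinom(n, 1, 0.7)

  # state trajectories (full 10 years; the observed span masks them later)
  states <- matrix(0L, n, 10)
  for (i in seq_len(n)) {
    cl <- cfg$classes[[class_names[latent[i]]]]
    P <- trans[[class_names[latent[i]]]]
    s <- sample.int(5L, 1L, prob = cl$init)
    states[i, 1] <- s
    for (t in 2:10) {
      s <- sample.int(5L, 1L, prob = P[s, ])
      states[i, t] <- s
    }
  }

  # item nonresponse inside the span
  item_missing <- matrix(FALSE, n, 10)
  if (cfg$mis_rate > 0) {
    item_missing[] <- runif(n * 10) < cfg$mis_rate
  }

  # hours and occupation
  full_timer <- rbinom(n, 1, 0.7) == 1
  occ_levels <- c("professional", "clerical", "service")
  primary_occ <- sample(occ_levels, n, replace = TRUE,
                        prob = c(0.40, 0.35, 0.25))

  person_id <- sprintf("P%05d", seq_len(n))
  pid_rep <- rep(person_id, each = 10)
  age_rep <- rep(ages, times = n)
  pos_rep <- rep(1:10, times = n)
  observed <- pos_rep >= rep(span_first, each = 10) &
    pos_rep <= rep(span_last, each = 10)
  st_idx <- as.vector(t(states))
  state <- .WS_WORK_STATES[st_idx]
  item_mis <- as.vector(t(item_missing)) & observed
  state[!observed | item_mis] <- NA_character_

  working <- !is.na(state) & state != "NW"
  hours <- numeric(length(state))
  hours[] <- NA_real_
  hours[!is.na(state) & state == "NW"] <- 0
  ft <- rep(full_timer, each = 10)
  n_work <- sum(working)
  raw_hours <- ifelse(ft[working],
                      pmax(35, rnorm(n_work, 42, 4)),
                      pmin(34, pmax(1, rnorm(n_work, 22, 6))))
  hours[working] <- round(raw_hours, 1)

  occupation <- rep(NA_character_, length(state))
  occ_draw <- runif(length(state))
  occ_base <- rep(primary_occ, each = 10)
  occupation[working] <- ifelse(
    occ_draw[working] < 0.9, occ_base[working],
    sample(occ_levels, sum(working), replace = TRUE))

  panel <- tibble::tibble(
    person_id = pid_rep, age = age_rep, state = state,
    weekly_hours = hours, occupation = occupation,
    observed = observed & !item_mis
  )

  education_obs <- education
  if (cfg$cov_missing_rate > 0) {
    education_obs[runif(n) < cfg$cov_missing_rate] <- NA_character_
  }
  covariates <- tibble::tibble(
    person_id = person_id, female = female, education = education_obs,
    partnered = partnered, baseline_age = cfg$window_start
  )

  # outcomes at the window-end age, on the standardized scale directly;
  # classes without a named entry in an effect vector get effect 0
  m <- cfg$outcome_model
  cls_nm <- class_names[latent]
  lk <- function(v) {
    out <- unname(v[cls_nm])
    out[is.na(out)] <- 0
    out
  }
  eff_phys <- lk(m$sf_physical) + lk(m$interaction_female) * female
  eff_ment <- lk(m$sf_mental) + lk(m$interaction_female) * female
  cov_lin <- m$beta_female * female +
    m$beta_edu_mid * (education == "mid") +
    m$beta_edu_high * (education == "high") +
    m$beta_partnered * partnered
  sf_physical <- m$intercept + eff_phys + cov_lin + rnorm(n, 0, m$resid_sd)
  sf_mental <- m$intercept + eff_ment + cov_lin + rnorm(n, 0, m$resid_sd)

  eta <- m$poor_fair_intercept + lk(m$poor_fair_logit)
  poor_fair <- rbinom(n, 1, plogis(eta))
  self_rated <- ifelse(poor_fair == 1,
                       sample(c("poor", "fair"), n, replace = TRUE,
                              prob = c(0.3, 0.7)),
                       sample(c("good", "very good", "excellent"), n,
                              replace = TRUE, prob = c(0.4, 0.35, 0.25)))
  distress_score <- pmin(50, pmax(10, m$distress_base +
    lk(m$distress_effects) + rnorm(n, 0, m$distress_sd)))
  outcomes <- tibble::tibble(
    person_id = person_id, outcome_age = cfg$window_start + 10L,
    sf_physical = sf_physical, sf_mental = sf_mental,
    self_rated = self_rated, poor_fair = poor_fair,
    distress_score = distress_score,
    distress_at_risk = distress_caseness(distress_score, m$instrument),
    instrument = m$instrument
  )

  truth <- tibble::tibble(
    person_id = person_id, latent_class = latent, class_name = cls_nm,
    injected_effect = lk(m$sf_physical),
    span_first = span_first, span_last = span_last
  )

  structure(list(panel = panel, covariates = covariates,
                 outcomes = outcomes, truth = truth,
                 config = cfg),
            class = "ws_sim")
}

#' @export
print.ws_sim <- function(x, ...) {
  cat("<ws_sim> synthetic panel:", nrow(x$truth), "persons,",
      nrow(x$panel), "person-years, window",
      x$config$window_start, "-", x$config$window_start + 9, "\n")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same units,
#' computed by the pair-counting formula on the contingency table. Equals 1
#' iff the partitions are identical up to relabeling; 0 in expectation for
#' independent random partitions.
#'
#' @param labels_a,labels_b Equal-length label vectors (any atomic type).
#' @return A number in \[-1, 1\].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions degenerate
  (sum_ij - expected) / (max_index - expected)
}
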