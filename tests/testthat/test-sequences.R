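test_that("encoding maps ages to positions and missingness to MIS", {
  p1 <- panel_from_states(rep("ST", 10))
  s1 <- encode_sequences(p1, c(25, 34))
  expect_equal(unlist(s1[1, paste0("p", 1:10)], use.names = FALSE),
               rep("ST", 10))

  # observed ages 27-34 only, all NW, inside window 25-34
  p2 <- panel_from_states(rep("NW", 8), start = 27)
  s2 <- encode_sequences(p2, c(25, 34))
  expect_equal(unlist(s2[1, paste0("p", 1:10)], use.names = FALSE),
               c("MIS", "MIS", rep("NW", 8)))
})

test_that("duplicate person-age records are rejected with offenders named", {
  p <- dplyr::bind_rows(panel_from_states(rep("ST", 10)),
                        panel_from_states("ST", start = 30))
  expect_error(encode_sequences(p, c(25, 34)), "A@30")
})

test_that("persons with no observed year in the window are dropped", {
  p <- dplyr::bind_rows(
    panel_from_states(rep("ST", 10), person_id = "A"),
    panel_from_states(rep(NA_character_, 10), person_id = "B"))
  s <- encode_sequences(p, c(25, 34))
  expect_equal(s$person_id, "A")
})

test_that("per-position state frequencies equal direct panel tabulation", {
  sim <- generate_panel(generator_config(n_persons = 120, seed = 21))
  seqs <- encode_sequences(sim$panel, c(25, 34))
  for (p in c(1, 5, 10)) {
    age <- 24 + p
    sub <- sim$panel[sim$panel$age == age, ]
    sub <- sub[sub$person_id %in% seqs$person_id, ]
    raw <- ifelse(sub$observed, sub$state, "MIS")
    oracle <- table(factor(raw, levels = c("NW", "ST", "EVE", "NGT",
                                           "ONS", "MIS")))
    enc <- table(factor(seqs[[paste0("p", p)]],
                        levels = c("NW", "ST", "EVE", "NGT", "ONS", "MIS")))
    expect_equal(as.numeric(enc), as.numeric(oracle))
  }
})

test_that("eligibility keeps sequences by longest consecutive observed run", {
  s <- make_seqs(list(
    rep("ST", 10),                                   # run 10 -> kept
    c(rep("ST", 6), rep("MIS", 4)),                  # run 6  -> dropped
    c(rep("ST", 7), "MIS", "ST", "MIS")))            # run 7  -> kept
  kept <- eligibility_filter(s, 7)
  expect_equal(kept$person_id, c("P001", "P003"))
  # threshold 1 keeps everything with at least one observed year
  expect_equal(nrow(eligibility_filter(s, 1)), 3)
  # monotone decreasing in the threshold
  sizes <- vapply(1:10, function(k) nrow(eligibility_filter(s, k)),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
  # filters only change membership, never content
  expect_identical(kept[1, ], s[1, ])
})

test_that("complete-case filter drops rows and reports per-field rates", {
  cov <- tibble::tibble(person_id = sprintf("P%02d", 1:10),
                        female = rep(0:1, 5),
                        education = c("low", rep("mid", 9)))
  out <- complete_case_filter(cov, c("female", "education"))
  expect_equal(nrow(out$data), 10)
  expect_equal(out$report$missing_rate, c(0, 0))

  cov$education[4] <- NA
  expect_warning(out2 <- complete_case_filter(cov, c("female", "education")),
                 "education")
  expect_equal(nrow(out2$data), 9)
  expect_equal(out2$report$missing_rate[out2$report$field == "education"], 0.1)
  expect_true(out2$report$flagged[out2$report$field == "education"])

  expect_error(complete_case_filter(cov, "income"), "income")
})

test_that("complete-case retained count equals a brute-force row scan", {
  set.seed(31)
  cov <- tibble::tibble(
    person_id = sprintf("P%03d", 1:200),
    a = ifelse(runif(200) < 0.03, NA, rnorm(200)),
    b = ifelse(runif(200) < 0.03, NA_character_, "x"))
  out <- complete_case_filter(cov, c("a", "b"))
  oracle <- sum(apply(cov[c("a", "b")], 1, function(r) !anyNA(r)))
  expect_equal(nrow(out$data), oracle)
})

test_that("primary hours classification follows the majority rule", {
  # ten years at 40 h -> full_time
  p <- panel_from_states(rep("ST", 10), hours = rep(40, 10))
  expect_equal(derive_primary_hours(p, c(25, 34))$primary_hours, "full_time")
  # 4 years at 20 h and 4 at 40 h -> exact tie -> mixed
  p2 <- panel_from_states(c(rep("ST", 8), rep("NW", 2)),
                          hours = c(rep(20, 4), rep(40, 4), 0, 0))
  expect_equal(derive_primary_hours(p2, c(25, 34))$primary_hours, "mixed")
  # no working years -> none
  p3 <- panel_from_states(rep("NW", 10), hours = rep(0, 10))
  expect_equal(derive_primary_hours(p3, c(25, 34))$primary_hours, "none")
  # negative hours rejected
  p$weekly_hours[3] <- -1
  expect_error(derive_primary_hours(p, c(25, 34)), "negative")
})

test_that("primary occupation follows the at-least-half rule with tie -> mixed", {
  occ <- c(rep("professional", 6), rep("service", 4))
  p <- panel_from_states(rep("ST", 10), occupation = occ)
  expect_equal(derive_primary_occupation(p, c(25, 34))$primary_occupation,
               "professional")
  occ2 <- c(rep("clerical", 5), rep("service", 5))
  p2 <- panel_from_states(rep("ST", 10), occupation = occ2)
  expect_equal(derive_primary_occupation(p2, c(25, 34))$primary_occupation,
               "mixed")
})

test_that("hours and occupation categories match a counting oracle on random panels", {
  set.seed(17)
  for (rep in 1:20) {
    n_obs <- sample(7:10, 1)
    states <- sample(c("ST", "NW", "EVE"), n_obs, replace = TRUE)
    hours <- ifelse(states == "NW", 0, sample(c(10, 20, 36, 45), n_obs,
                                              replace = TRUE))
    occ <- ifelse(states == "NW", NA_character_,
                  sample(c("professional", "clerical", "service"), n_obs,
                         replace = TRUE))
    p <- panel_from_states(states, hours = hours, occupation = occ)
    got_h <- derive_primary_hours(p, c(25, 34))$primary_hours
    got_o <- derive_primary_occupation(p, c(25, 34))$primary_occupation

    hc <- ifelse(hours[states != "NW"] >= 35, "full_time", "part_time")
    oracle_h <- if (length(hc) == 0) "none" else {
      tab <- sort(table(hc), decreasing = TRUE)
      if (length(tab) == 2 && tab[1] == tab[2]) "mixed" else names(tab)[1]
    }
    expect_equal(got_h, oracle_h)

    oc <- occ[!is.na(occ)]
    oracle_o <- if (length(oc) == 0) "none" else {
      tab <- sort(table(oc), decreasing = TRUE)
      if (length(tab) > 1 && tab[1] == tab[2]) "mixed"
      else if (tab[1] >= length(oc) / 2) names(tab)[1] else "mixed"
    }
    expect_equal(got_o, oracle_o)
  }
})

test_that("wide write/read round trip reproduces sequences exactly", {
  sim <- generate_panel(generator_config(n_persons = 40, seed = 8))
  seqs <- encode_sequences(sim$panel, c(25, 34))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(seqs, path)
  back <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(seqs),
               ignore_attr = "window")
})
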