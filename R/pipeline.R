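#' Pipeline configuration
#'
#' Collects every tunable the end-to-end run needs. Defaults honor the
#' standard procedural constants: indel cost 1, eligibility threshold 7
#' consecutive observed years, full-time boundary 35 h/wk, candidate cluster
#' counts 4-8, outcomes at the window-end age (e.g. ages 25-34 with outcomes
#' at 35; `outcome_offset = 5` accommodates designs whose health modules run
#' five years later).
#'
#' @param windows List of `c(start_age, outcome_age)` pairs; default
#'   `list(c(25, 35), c(35, 45), c(45, 55))`. Windows must not overlap.
#' @param outcome_offset Added to every outcome age (default 0; use 5 for
#'   the later-module convention).
#' @param indel Insertion/deletion cost (default 1).
#' @param min_consecutive Eligibility threshold in consecutive observed
#'   years (default 7).
#' @param full_time_hours Full-time boundary in hours/week (default 35).
#' @param k_range Candidate cluster counts (default 4:8).
#' @param force_k Optional explicit cluster count (>= 2).
#' @param label_thresholds See [label_thresholds()].
#' @param covariates Adjustment covariates for the regressions.
#' @param linear_outcomes,binary_outcomes Outcome columns by family.
#' @param standardize_outcomes Standardize the linear outcomes to mean 50 /
#'   SD 10 within the analysis sample before fitting (default `TRUE`).
#' @param denominator Denominator rule for primary hours/occupation
#'   (`"observed"` or `"fixed10"`).
#' @param instrument Distress instrument name (`"K10"`, `"GHQ12"`, `"CESD"`).
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the input panel is simulated).
#' @return A list of class `ws_pipeline_config`.
#' @export
pipeline_config <- function(windows = list(c(25, 35), c(35, 45), c(45, 55)),
                            outcome_offset = 0,
                            indel = 1,
                            min_consecutive = 7,
                            full_time_hours = 35,
                            k_range = 4:8,
                            force_k = NULL,
                            label_thresholds = workseq::label_thresholds(),
                            covariates = c("female", "education", "partnered",
                                           "primary_hours"),
                            linear_outcomes = c("sf_physical", "sf_mental"),
                            binary_outcomes = c("poor_fair",
                                                "distress_at_risk"),
                            standardize_outcomes = TRUE,
                            denominator = "observed",
                            instrument = "K10",
                            seed = 1L) {
  if (!is.null(force_k) && force_k < 2) {
    stop("force_k must be at least 2 (a single cluster is not a solution)",
         call. = FALSE)
  }
  starts <- vapply(windows, `[`, numeric(1), 1)
  if (anyDuplicated(starts) ||
      any(diff(sort(starts)) < 10 & length(starts) > 1)) {
    stop("sequence windows must not overlap (starts at least 10 years apart)",
         call. = FALSE)
  }
  structure(list(
    windows = lapply(windows, function(w) c(w[1], w[2] + outcome_offset)),
    indel = indel, min_consecutive = min_consecutive,
    full_time_hours = full_time_hours, k_range = k_range, force_k = force_k,
    label_thresholds = label_thresholds, covariates = covariates,
    linear_outcomes = linear_outcomes, binary_outcomes = binary_outcomes,
    standardize_outcomes = standardize_outcomes, denominator = denominator,
    instrument = instrument, seed = as.integer(seed)
  ), class = "ws_pipeline_config")
}

#' Validate pipeline input tables
#'
#' Schema and invariant checks run before any computation: required columns,
#' duplicate (person, age) records, unknown state codes, negative weekly
#' hours, duplicated person ids in the person-level tables. Problems are
#' reported, not thrown.
#'
#' @param panel Long-format person-year tibble.
#' @param covariates,outcomes Optional person-level tibbles.
#' @return A tibble of problems (table, check, id, message); zero rows means
#'   the inputs are valid.
#' @export
validate_inputs <- function(panel, covariates = NULL, outcomes = NULL) {
  problems <- list()
  add <- function(table, check, id, message) {
    problems[[length(problems) + 1]] <<- tibble::tibble(
      table = table, check = check, id = as.character(id), message = message)
  }
  need <- setdiff(c("person_id", "age", "state"), names(panel))
  if (length(need) > 0) {
    add("panel", "columns", NA, paste("missing column(s):",
                                      paste(need, collapse = ", ")))
    return(dplyr::bind_rows(problems))
  }
  dup <- dplyr::count(panel, .data$person_id, .data$age) |>
    dplyr::filter(.data$n > 1)
  for (i in seq_len(nrow(dup))) {
    add("panel", "duplicate_record", paste0(dup$person_id[i], "@", dup$age[i]),
        "more than one record for this (person_id, age)")
  }
  bad_state <- !is.na(panel$state) & !panel$state %in% .WS_STATES
  for (i in which(bad_state)) {
    add("panel", "unknown_state", paste0(panel$person_id[i], "@", panel$age[i]),
        paste("unknown state code:", panel$state[i]))
  }
  if ("weekly_hours" %in% names(panel)) {
    neg <- !is.na(panel$weekly_hours) & panel$weekly_hours < 0
    for (i in which(neg)) {
      add("panel", "negative_hours",
          paste0(panel$person_id[i], "@", panel$age[i]),
          paste("negative weekly_hours:", panel$weekly_hours[i]))
    }
  }
  for (nm in c("covariates", "outcomes")) {
    tb <- if (nm == "covariates") covariates else outcomes
    if (is.null(tb)) next
    if (!"person_id" %in% names(tb)) {
      add(nm, "columns", NA, "missing column: person_id")
      next
    }
    dup_id <- unique(tb$person_id[duplicated(tb$person_id)])
    for (id in dup_id) add(nm, "duplicate_person", id, "duplicated person_id")
  }
  if (length(problems) == 0) {
    return(tibble::tibble(table = character(), check = character(),
                          id = character(), message = character()))
  }
  dplyr::bind_rows(problems)
}

#' Run the full trajectory-to-health pipeline
#'
#' Executes, for each configured (window, outcome-age) pair with data:
#' sequence encoding, the consecutive-years eligibility filter, the
#' complete-case covariate filter, primary hours/occupation derivation,
#' transition-rate estimation, the substitution-cost model, pairwise
#' optimal-matching distances, Ward clustering with stopping indices,
#' cluster profiling and labelling, outcome standardization, and the
#' cluster-outcome regressions (reference: the mainly-ST cluster). All
#' artifacts are written as delimited text plus a JSON manifest; a rerun on
#' identical inputs and config is byte-identical.
#'
#' @param panel Long-format person-year tibble (see [generate_panel()] for
#'   the expected columns).
#' @param covariates Person-level covariate tibble.
#' @param outcomes Person-level outcome tibble with an `outcome_age` column.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed). `NULL` skips writing.
#' @return A list of class `ws_run`: per-window results (`sequences`,
#'   `cost_model`, `distances`, `solution`, `profiles`, `fits`, `effects`,
#'   `analysis`) plus `manifest`.
#' @export
run_pipeline <- function(panel, covariates, outcomes,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "ws_pipeline_config"))
  stage <- "validate"
  res <- tryCatch({
    problems <- validate_inputs(panel, covariates, outcomes)
    if (nrow(problems) > 0) {
      stop(nrow(problems), " validation problem(s); first: ",
           problems$message[1], " [", problems$table[1], " ",
           problems$id[1], "]", call. = FALSE)
    }
    windows_res <- list()
    for (w in config$windows) {
      window <- c(w[1], w[1] + 9)
      outcome_age <- w[2]
      if (!any(panel$age >= window[1] & panel$age <= window[2] &
                 (!"observed" %in% names(panel) | panel$observed))) next
      stage <- paste0("window_", window[1])
      windows_res[[as.character(window[1])]] <-
        run_window(panel, covariates, outcomes, window, outcome_age, config)
    }
    if (length(windows_res) == 0) {
      stop("no configured window overlaps the panel ages", call. = FALSE)
    }
    windows_res
  }, error = function(e) {
    stop("pipeline stage [", stage, "] failed: ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(
    package = "workseq",
    version = as.character(utils::packageVersion("workseq")),
    seed = config$seed,
    config_hash = rlang::hash(list(config = unclass(config))),
    input_hash = rlang::hash(list(panel = panel, covariates = covariates,
                                  outcomes = outcomes)),
    constants = list(indel = config$indel,
                     min_consecutive_years = config$min_consecutive,
                     full_time_hours = config$full_time_hours),
    windows = names(res),
    stages = c("validate", "encode", "eligibility", "complete_case",
               "primary_hours", "primary_occupation", "transition_rates",
               "cost_model", "distances", "ward", "select_k", "profiles",
               "outcomes", "regression")
  )
  out <- structure(list(windows = res, manifest = manifest), class = "ws_run")
  if (!is.null(out_dir)) write_run_artifacts(out, out_dir)
  out
}

run_window <- function(panel, covariates, outcomes, window, outcome_age,
                       config) {
  seqs <- encode_sequences(panel, window)
  seqs <- eligibility_filter(seqs, config$min_consecutive)
  if (nrow(seqs) < 3) {
    stop("fewer than 3 eligible sequences in window ",
         window[1], "-", window[2], call. = FALSE)
  }
  hours <- derive_primary_hours(panel, window, config$full_time_hours,
                                config$denominator)
  occ <- derive_primary_occupation(panel, window, config$denominator)
  cov <- covariates |>
    dplyr::left_join(hours, by = "person_id") |>
    dplyr::left_join(occ, by = "person_id") |>
    dplyr::filter(.data$person_id %in% seqs$person_id)
  cc <- complete_case_filter(cov, setdiff(names(cov), "person_id"))
  cov <- cc$data
  seqs <- seqs[seqs$person_id %in% cov$person_id, , drop = FALSE]

  trate <- estimate_transition_rates(seqs)
  costs <- build_cost_model(trate, indel = config$indel)
  D <- pairwise_distances(seqs, costs)
  dend <- ward_linkage(D)
  solution <- select_k(dend, D, k_range = config$k_range,
                       force_k = config$force_k)
  profiles <- profile_clusters(solution, seqs, cov,
                               thresholds = config$label_thresholds)

  # analysis table: cluster labels + covariates + window outcomes
  labels_vec <- vapply(profiles, `[[`, character(1), "label")
  if (anyDuplicated(labels_vec)) {  # disambiguate so clusters never merge
    dup <- labels_vec %in% labels_vec[duplicated(labels_vec)]
    labels_vec[dup] <- paste0(labels_vec[dup], " [",
                              vapply(profiles, `[[`, integer(1),
                                     "cluster")[dup], "]")
  }
  label_map <- setNames(labels_vec,
                        vapply(profiles, `[[`, integer(1), "cluster"))
  analysis <- tidy(solution) |>
    dplyr::mutate(cluster_label = unname(label_map[as.character(.data$cluster)])) |>
    dplyr::inner_join(cov, by = "person_id") |>
    dplyr::inner_join(
      dplyr::filter(outcomes, .data$outcome_age == !!outcome_age),
      by = "person_id")

  if (config$standardize_outcomes) {
    for (oc in config$linear_outcomes) {
      if (oc %in% names(analysis) &&
          length(unique(analysis[[oc]][is.finite(analysis[[oc]])])) >= 2) {
        analysis[[oc]] <- standardize_sf(analysis[[oc]])
      }
    }
  }

  sizes <- vapply(profiles, `[[`, integer(1), "size")
  reference <- reference_cluster_from(labels_vec, sizes)
  fits <- list()
  effects <- list()
  for (oc in c(config$linear_outcomes, config$binary_outcomes)) {
    if (!oc %in% names(analysis)) next
    fam <- if (oc %in% config$linear_outcomes) "linear" else "logistic"
    spec <- model_spec(oc, family = fam, exposure = "cluster_label",
                       reference = reference,
                       covariates = intersect(config$covariates,
                                              names(analysis)))
    fit <- tryCatch(
      if (fam == "linear") fit_linear(spec, analysis)
      else fit_logistic(spec, analysis),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("model for '", oc, "' failed: ", conditionMessage(fit),
              call. = FALSE)
      next
    }
    fits[[oc]] <- fit
    effects[[oc]] <- dplyr::mutate(tidy(fit), outcome = oc,
                                   family = fam, .before = 1)
  }

  list(window = window, outcome_age = outcome_age, sequences = seqs,
       covariates = cov, complete_case_report = cc$report,
       transition_rates = trate, cost_model = costs, distances = D,
       dendrogram = dend, solution = solution, profiles = profiles,
       reference = reference, analysis = analysis, fits = fits,
       effects = dplyr::bind_rows(effects))
}

# Pick the reference cluster: the largest ST-dominant cluster ("ST only" /
# "mainly ST"); fall back to the largest cluster with a warning.
reference_cluster_from <- function(labels_vec, sizes) {
  st <- grepl("^(mainly ST|ST only)", labels_vec)
  if (any(st)) {
    return(labels_vec[st][which.max(sizes[st])])
  }
  warning("no mainly-ST cluster found; using the largest cluster ('",
          labels_vec[which.max(sizes)], "') as reference", call. = FALSE)
  labels_vec[which.max(sizes)]
}

#' @export
print.ws_run <- function(x, ...) {
  cat("<ws_run>", length(x$windows), "window(s); config hash",
      x$manifest$config_hash, "\n")
  for (nm in names(x$windows)) {
    w <- x$windows[[nm]]
    cat("  window ", w$window[1], "-", w$window[2], ": ",
        nrow(w$sequences), " sequences, k = ", w$solution$k,
        ", ref '", w$reference, "'\n", sep = "")
  }
  invisible(x)
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(run$windows)) {
    w <- run$windows[[nm]]
    pfx <- file.path(out_dir, paste0("w", nm, "_"))
    readr::write_csv(w$sequences, paste0(pfx, "sequences.csv"))
    readr::write_csv(tibble::as_tibble(w$transition_rates$rates,
                                       rownames = "from"),
                     paste0(pfx, "transition_rates.csv"))
    readr::write_csv(tibble::as_tibble(w$cost_model$sub, rownames = "state"),
                     paste0(pfx, "substitution_costs.csv"))
    write_distance_matrix(w$distances, paste0(pfx, "distances.csv"))
    readr::write_csv(w$dendrogram$merges, paste0(pfx, "dendrogram.csv"))
    readr::write_csv(tidy(w$solution), paste0(pfx, "assignments.csv"))
    readr::write_csv(w$solution$diagnostics, paste0(pfx, "diagnostics.csv"))
    readr::write_csv(tidy(w$profiles), paste0(pfx, "profiles.csv"))
    readr::write_csv(profile_plot_data(w$profiles),
                     paste0(pfx, "plot_data.csv"))
    readr::write_csv(w$complete_case_report,
                     paste0(pfx, "complete_case_report.csv"))
    if (nrow(w$effects) > 0) {
      readr::write_csv(w$effects, paste0(pfx, "effects.csv"))
      summary_cells <- purrr::map_dfr(names(w$fits), function(oc) {
        dplyr::mutate(effect_size_report(w$fits[[oc]]), outcome = oc,
                      .before = 1)
      })
      readr::write_csv(summary_cells, paste0(pfx, "significant_cells.csv"))
    }
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(data_dictionary_text(), file.path(out_dir, "data_dictionary.txt"))
  invisible(out_dir)
}

data_dictionary_text <- function() {
  c("workseq artifact data dictionary",
    "",
    "w<START>_sequences.csv: person_id + p1..p10 state codes (NW, ST, EVE, NGT, ONS, MIS) for window starting at age <START>",
    "w<START>_transition_rates.csv: 6x6 pooled transition rates, row = origin state",
    "w<START>_substitution_costs.csv: 6x6 symmetric substitution costs (TRATE: 2*indel - p(a->b) - p(b->a))",
    "w<START>_distances.csv: square optimal-matching distance matrix, id header row/column, full double precision",
    "w<START>_dendrogram.csv: Ward merge list (step, left, right, height_ss = within-SS increase, size)",
    "w<START>_assignments.csv: person_id, cluster",
    "w<START>_diagnostics.csv: k, ch (Calinski-Harabasz pseudo-F), dh_ratio, dh_pseudo_t2 (Duda-Hart for the k -> k+1 split)",
    "w<START>_profiles.csv: cluster, label, size, share, mean_transitions, modal sequence",
    "w<START>_plot_data.csv: cluster, label, position (1-10), state, frequency — sequence-distribution plot data",
    "w<START>_complete_case_report.csv: field, n_missing, missing_rate, flagged (> 5%)",
    "w<START>_effects.csv: outcome, family, term, estimate, std.error, statistic, p.value, n, effect_size_sd (linear only; estimate / 10)",
    "w<START>_significant_cells.csv: display cells — rounded point effects (linear) or +/- symbols (logistic), blank when p >= 0.05",
    "manifest.json: package version, seed, config/input hashes, procedural constants, stage list")
}

#' Write the simulated tables as delimited text
#'
#' Writes panel, covariates, outcomes, truth, and a data dictionary to a
#' directory, mirroring the long-format exchange layout the pipeline reads.
#'
#' @param sim A `ws_sim` from [generate_panel()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_sim <- function(sim, out_dir) {
  stopifnot(inherits(sim, "ws_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$panel, file.path(out_dir, "panel.csv"))
  readr::write_csv(sim$covariates, file.path(out_dir, "covariates.csv"))
  readr::write_csv(sim$outcomes, file.path(out_dir, "outcomes.csv"))
  readr::write_csv(sim$truth, file.path(out_dir, "truth.csv"))
  writeLines(c(
    "panel.csv: person_id, age, state (NW/ST/EVE/NGT/ONS or empty), weekly_hours, occupation, observed",
    "covariates.csv: person_id, female (0/1), education (low/mid/high), partnered (0/1), baseline_age",
    "outcomes.csv: person_id, outcome_age, sf_physical, sf_mental, self_rated, poor_fair, distress_score, distress_at_risk, instrument",
    "truth.csv: person_id, latent_class, class_name, injected_effect (points on sf_physical), span_first, span_last"),
    file.path(out_dir, "data_dictionary.txt"))
  invisible(out_dir)
}

#' Read simulated tables back from a directory
#'
#' @param dir Directory written by [write_sim()].
#' @return A list with `panel`, `covariates`, `outcomes`, `truth`.
#' @export
read_sim <- function(dir) {
  read1 <- function(f, types) {
    readr::read_csv(file.path(dir, f), col_types = types, progress = FALSE)
  }
  list(
    panel = read1("panel.csv", readr::cols(
      person_id = "c", age = "i", state = "c", weekly_hours = "d",
      occupation = "c", observed = "l")),
    covariates = read1("covariates.csv", readr::cols(
      person_id = "c", female = "i", education = "c", partnered = "i",
      baseline_age = "i")),
    outcomes = read1("outcomes.csv", readr::cols(
      person_id = "c", outcome_age = "i", sf_physical = "d", sf_mental = "d",
      self_rated = "c", poor_fair = "i", distress_score = "d",
      distress_at_risk = "i", instrument = "c")),
    truth = read1("truth.csv", readr::cols(
      person_id = "c", latent_class = "i", class_name = "c",
      injected_effect = "d", span_first = "i", span_last = "i"))
  )
}
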