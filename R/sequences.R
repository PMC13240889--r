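#' Build fixed-length work-schedule sequences from a person-year panel
#'
#' Maps each person's records inside a 10-year age window onto a length-10
#' state vector. Position `p` holds the state at age `window[1] + p - 1`;
#' unobserved years (panel attrition) and item-missing years both map to the
#' `MIS` state. Persons with no observed year in the window are dropped.
#'
#' @param panel Long-format tibble with columns `person_id`, `age`, `state`
#'   (alphabet code or `NA`), and optionally `observed`.
#' @param window Length-2 integer vector `c(start_age, end_age)` with
#'   `end_age = start_age + 9`, e.g. `c(25, 34)`.
#' @return A wide tibble with `person_id` and state columns `p1` .. `p10`,
#'   carrying the window as attribute `window`.
#' @examples
#' panel <- tibble::tibble(person_id = "A", age = 25:34, state = "ST",
#'                         observed = TRUE)
#' encode_sequences(panel, c(25, 34))
#' @export
encode_sequences <- function(panel, window) {
  stopifnot(length(window) == 2)
  window <- as.integer(window)
  if (window[2] - window[1] != 9L) {
    stop("window must span exactly 10 ages (start, start + 9)", call. = FALSE)
  }
  sub <- dplyr::filter(panel, .data$age >= window[1], .data$age <= window[2])
  dup <- dplyr::count(sub, .data$person_id, .data$age) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (person_id, age) records: ",
         paste(head(paste0(dup$person_id, "@", dup$age), 5), collapse = ", "),
         if (nrow(dup) > 5) " ..." else "", call. = FALSE)
  }
  if ("observed" %in% names(sub)) {
    sub$state[!sub$observed] <- NA_character_
  }
  known <- sub$state[!is.na(sub$state)]
  bad <- setdiff(unique(known), .WS_STATES)
  if (length(bad) > 0) {
    stop("unknown state code(s) in panel: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sub$state[is.na(sub$state)] <- "MIS"
  sub$position <- paste0("p", sub$age - window[1] + 1L)
  wide <- tidyr::pivot_wider(
    dplyr::select(sub, "person_id", "position", "state"),
    names_from = "position", values_from = "state")
  for (cl in seq_cols()) {
    if (!cl %in% names(wide)) wide[[cl]] <- "MIS"
    wide[[cl]][is.na(wide[[cl]])] <- "MIS"
  }
  wide <- dplyr::select(wide, "person_id", dplyr::all_of(seq_cols()))
  all_mis <- rowSums(as.matrix(wide[seq_cols()]) != "MIS") == 0
  wide <- wide[!all_mis, , drop = FALSE]
  wide <- dplyr::arrange(wide, .data$person_id)
  attr(wide, "window") <- window
  wide
}

# Longest run of consecutive non-MIS positions in one state vector.
longest_observed_run <- function(states) {
  obs <- states != "MIS"
  if (!any(obs)) return(0L)
  r <- rle(obs)
  max(r$lengths[r$values])
}

#' Eligibility filter: minimum consecutive observed years
#'
#' Retains sequences whose longest run of consecutive non-`MIS` positions is
#' at least `min_consecutive` (default 7, the usual panel-eligibility rule:
#' people must be observed for 7 or more consecutive years of the 10-year
#' window).
#'
#' @param sequences Wide sequence tibble from [encode_sequences()].
#' @param min_consecutive Required run length, in 1..10.
#' @return The retained subset, same shape and attributes.
#' @export
eligibility_filter <- function(sequences, min_consecutive = 7) {
  stopifnot(min_consecutive >= 1, min_consecutive <= 10)
  m <- as.matrix(sequences[seq_cols()])
  runs <- apply(m, 1, longest_observed_run)
  out <- sequences[runs >= min_consecutive, , drop = FALSE]
  attr(out, "window") <- attr(sequences, "window")
  out
}

#' Complete-case filter with a per-field missingness report
#'
#' Drops rows with any missing value in the required fields and reports the
#' per-field missing rate. Rates above 5% are flagged with a warning (the
#' complete-case approach is only defensible at low missingness) but the
#' filter still runs.
#'
#' @param covariates Tibble of person-level covariates.
#' @param required_fields Character vector of column names that must be
#'   non-missing.
#' @param warn_rate Missing-rate threshold that triggers a warning
#'   (default 0.05).
#' @return A list with `data` (the retained rows) and `report` (tibble:
#'   field, n_missing, missing_rate, flagged).
#' @export
complete_case_filter <- function(covariates, required_fields,
                                 warn_rate = 0.05) {
  unknown <- setdiff(required_fields, names(covariates))
  if (length(unknown) > 0) {
    stop("required field(s) not in table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(covariates)
  report <- tibble::tibble(
    field = required_fields,
    n_missing = vapply(required_fields,
                       function(f) sum(is.na(covariates[[f]])), integer(1),
                       USE.NAMES = FALSE),
    missing_rate = .data$n_missing / max(n, 1L)
  )
  report$flagged <- report$missing_rate > warn_rate
  if (any(report$flagged)) {
    warning("missing rate exceeds ", warn_rate * 100, "% for: ",
            paste(report$field[report$flagged], collapse = ", "),
            call. = FALSE)
  }
  keep <- complete.cases(covariates[required_fields])
  list(data = covariates[keep, , drop = FALSE], report = report)
}

# Shared majority rule for primary hours / occupation: a category is primary
# when it covers at least half of the person's counted years; an exact tie
# between the top categories gives "mixed".
majority_category <- function(categories) {
  categories <- categories[!is.na(categories)]
  if (length(categories) == 0) return(NA_character_)
  tab <- sort(table(categories), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return("mixed")
  if (tab[1] >= length(categories) / 2) return(names(tab)[1])
  "mixed"
}

#' Derive each person's primary weekly-hours category over a window
#'
#' Each observed working year is classed full-time (>= 35 h/wk) or part-time
#' (1-34 h/wk). A person is `full_time` or `part_time` when that class covers
#' at least half of their observed working years; an exactly equal share gives
#' `mixed`; a person with no working years is `none`. The denominator is the
#' person's observed working years (configurable to the fixed 10-year window
#' via `denominator = "fixed10"`, under which persons observed fewer than 10
#' years can only reach a majority if one class covers >= 5 years).
#'
#' @param panel Long-format person-year tibble with `weekly_hours`.
#' @param window `c(start_age, end_age)` as in [encode_sequences()].
#' @param full_time_hours Full-time boundary in hours/week (default 35).
#' @param denominator `"observed"` (default) or `"fixed10"`.
#' @return Tibble `person_id`, `primary_hours`.
#' @export
derive_primary_hours <- function(panel, window, full_time_hours = 35,
                                 denominator = c("observed", "fixed10")) {
  denominator <- match.arg(denominator)
  sub <- window_records(panel, window)
  if (any(sub$weekly_hours < 0, na.rm = TRUE)) {
    bad <- unique(sub$person_id[!is.na(sub$weekly_hours) &
                                  sub$weekly_hours < 0])
    stop("negative weekly_hours for person(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  sub$hours_class <- dplyr::case_when(
    is.na(sub$weekly_hours) | sub$weekly_hours == 0 ~ NA_character_,
    sub$weekly_hours >= full_time_hours ~ "full_time",
    TRUE ~ "part_time"
  )
  per_person(sub, "hours_class", denominator, none = "none",
             out_col = "primary_hours")
}

#' Derive each person's primary occupation over a window
#'
#' The primary occupation is the one held for at least half of the counted
#' years; exactly equal shares give `"mixed"`; no working years give
#' `"none"`. Denominator semantics as in [derive_primary_hours()].
#'
#' @inheritParams derive_primary_hours
#' @return Tibble `person_id`, `primary_occupation`.
#' @export
derive_primary_occupation <- function(panel, window,
                                      denominator = c("observed", "fixed10")) {
  denominator <- match.arg(denominator)
  sub <- window_records(panel, window)
  per_person(sub, "occupation", denominator, none = "none",
             out_col = "primary_occupation")
}

window_records <- function(panel, window) {
  sub <- dplyr::filter(panel, .data$age >= window[1], .data$age <= window[2])
  if ("observed" %in% names(sub)) sub <- dplyr::filter(sub, .data$observed)
  sub
}

per_person <- function(sub, col, denominator, none, out_col) {
  res <- sub |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(cat = {
      x <- .data[[col]]
      x <- x[!is.na(x)]
      if (length(x) == 0) {
        none
      } else if (denominator == "fixed10") {
        tab <- sort(table(x), decreasing = TRUE)
        if (length(tab) > 1 && tab[1] == tab[2]) "mixed"
        else if (tab[1] >= 5) names(tab)[1]
        else "mixed"
      } else {
        majority_category(x)
      }
    }, .groups = "drop")
  names(res)[names(res) == "cat"] <- out_col
  res
}
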