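# The six-letter schedule-state alphabet used throughout the package.
# MIS (missing) is always the sixth and last code.

.WS_STATES <- c("NW", "ST", "EVE", "NGT", "ONS", "MIS")
.WS_WORK_STATES <- c("NW", "ST", "EVE", "NGT", "ONS")

#' The work-schedule state alphabet
#'
#' Six ordered state codes describe a person-year of work scheduling:
#' `NW` not working, `ST` standard daytime hours, `EVE` evenings (3-9 pm),
#' `NGT` nights (9 pm-6 am), `ONS` other nonstandard schedules (irregular
#' hours or weekends), and `MIS` missingness (the sixth state, always last).
#' Missing person-years are carried as an ordinary state so that panel
#' attrition itself becomes part of a trajectory.
#'
#' @param include_missing Keep the `MIS` code (default `TRUE`).
#' @return A tibble with columns `code` and `description`, in alphabet order.
#' @examples
#' schedule_states()
#' @export
schedule_states <- function(include_missing = TRUE) {
  out <- tibble::tibble(
    code = .WS_STATES,
    description = c(
      "not working",
      "standard daytime hours",
      "evenings (3-9 pm)",
      "nights (9 pm-6 am)",
      "other nonstandard (irregular hours or weekends)",
      "missing"
    )
  )
  if (!include_missing) out <- out[out$code != "MIS", ]
  out
}

# Map state codes to 1-based alphabet indices, erroring on unknown codes.
state_index <- function(states) {
  idx <- match(states, .WS_STATES)
  if (anyNA(idx)) {
    bad <- unique(states[is.na(idx)])
    stop("unknown state code(s): ", paste(bad, collapse = ", "),
         " (alphabet: ", paste(.WS_STATES, collapse = ", "), ")",
         call. = FALSE)
  }
  idx
}

# Column names of the 10 sequence positions in wide tables.
seq_cols <- function() paste0("p", 1:10)

# Extract the n x 10 integer state matrix from a wide sequence tibble.
seq_matrix <- function(sequences) {
  cols <- seq_cols()
  missing_cols <- setdiff(cols, names(sequences))
  if (length(missing_cols) > 0) {
    stop("sequence table lacks position column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m <- vapply(cols, function(cl) state_index(sequences[[cl]]),
              integer(nrow(sequences)))
  if (nrow(sequences) == 1L) m <- matrix(m, nrow = 1L)
  rownames(m) <- as.character(sequences$person_id)
  m
}
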