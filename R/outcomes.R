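#' Standardize SF physical/mental function scores to mean 50, SD 10
#'
#' `50 + 10 * (x - mean(x)) / sd(x)` with the n-1 sample standard deviation,
#' so the output has sample mean exactly 50 and sample SD exactly 10 (to
#' floating tolerance) and a one-point contrast on the output corresponds to
#' one tenth of a standard deviation. Affine-invariant and idempotent.
#'
#' @param raw_scores Numeric vector with at least 2 distinct finite values.
#' @return The standardized vector.
#' @examples
#' standardize_sf(c(0, 10))  # 42.93, 57.07
#' @export
standardize_sf <- function(raw_scores) {
  x <- as.numeric(raw_scores)
  if (any(!is.finite(x))) stop("scores must be finite", call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("cannot standardize a constant vector (zero variance)",
         call. = FALSE)
  }
  50 + 10 * (x - mean(x)) / sd(x)
}

.SELF_RATED_LEVELS <- c("poor", "fair", "good", "very good", "excellent")

#' Dichotomize self-rated general health
#'
#' Collapses the five-level self-rated health item to poor/fair (1) versus
#' otherwise (0).
#'
#' @param health_category Character vector over
#'   poor / fair / good / very good / excellent (case-insensitive).
#' @return Integer 0/1 vector (`NA` in, `NA` out).
#' @export
dichotomize_self_rated <- function(health_category) {
  x <- tolower(trimws(as.character(health_category)))
  bad <- setdiff(unique(x[!is.na(x)]), .SELF_RATED_LEVELS)
  if (length(bad) > 0) {
    stop("unknown self-rated health categories: ",
         paste(bad, collapse = ", "), " (expected: ",
         paste(.SELF_RATED_LEVELS, collapse = ", "), ")", call. = FALSE)
  }
  ifelse(is.na(x), NA_integer_, as.integer(x %in% c("poor", "fair")))
}

.INSTRUMENTS <- list(
  K10 = list(range = c(10, 50), threshold = 22),
  GHQ12 = list(range = c(0, 12), threshold = 4),
  CESD = list(range = c(0, 60), threshold = 16)
)

#' Psychological-distress caseness from an instrument score
#'
#' Flags a person as at risk (1) when the distress score reaches the
#' instrument's caseness cutoff: Kessler-10 >= 22, GHQ-12 (0-0-1-1 caseness
#' scoring) >= 4, CES-D >= 16. These conventional cutoffs are configurable.
#'
#' @param score Numeric score(s) within the instrument range
#'   (K10: 10-50, GHQ12: 0-12, CESD: 0-60).
#' @param instrument One of `"K10"`, `"GHQ12"`, `"CESD"`.
#' @param threshold Optional override of the default cutoff.
#' @return Integer 0/1 vector (`NA` in, `NA` out).
#' @examples
#' distress_caseness(c(10, 22, 35), "K10")
#' @export
distress_caseness <- function(score, instrument = c("K10", "GHQ12", "CESD"),
                              threshold = NULL) {
  instrument <- match.arg(instrument)
  spec <- .INSTRUMENTS[[instrument]]
  if (is.null(threshold)) threshold <- spec$threshold
  ok <- is.na(score) | (score >= spec$range[1] & score <= spec$range[2])
  if (!all(ok)) {
    stop("score out of range for ", instrument, " (valid: ",
         spec$range[1], "-", spec$range[2], "): ",
         paste(head(score[!ok], 5), collapse = ", "), call. = FALSE)
  }
  ifelse(is.na(score), NA_integer_, as.integer(score >= threshold))
}
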