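#' Pooled transition rates between schedule states
#'
#' Counts all adjacent-position pairs (t, t+1) across persons and positions
#' and normalizes each origin row. `MIS` participates as an ordinary state:
#' moving into missingness is a transition like any other. States never
#' observed as an origin are flagged rather than imputed.
#'
#' @param sequences Wide sequence tibble from [encode_sequences()], or a
#'   character matrix of state codes (rows = persons).
#' @return An object of class `ws_trate`: list with `rates` (6x6,
#'   row-stochastic where observed), `counts`, `origin_totals`, and
#'   `unobserved` (logical per state).
#' @export
estimate_transition_rates <- function(sequences) {
  m <- as_state_matrix(sequences)
  if (nrow(m) == 0) stop("no sequences supplied", call. = FALSE)
  k <- length(.WS_STATES)
  counts <- matrix(0, k, k, dimnames = list(.WS_STATES, .WS_STATES))
  mi <- matrix(state_index(as.vector(m)), nrow = nrow(m))
  L <- ncol(mi)
  from <- as.vector(mi[, -L, drop = FALSE])
  to <- as.vector(mi[, -1, drop = FALSE])
  tab <- table(factor(from, levels = seq_len(k)),
               factor(to, levels = seq_len(k)))
  counts[] <- as.numeric(tab)
  origin_totals <- rowSums(counts)
  rates <- counts / ifelse(origin_totals > 0, origin_totals, 1)
  rates[origin_totals == 0, ] <- 0
  structure(list(rates = rates, counts = counts,
                 origin_totals = origin_totals,
                 unobserved = origin_totals == 0),
            class = "ws_trate")
}

#' @export
print.ws_trate <- function(x, ...) {
  cat("<ws_trate> pooled transition rates (",
      sum(x$origin_totals), " adjacent pairs)\n", sep = "")
  print(round(x$rates, 3))
  invisible(x)
}

#' Substitution-cost model from transition rates (TRATE convention)
#'
#' For distinct states a, b the substitution cost is
#' `2 * indel - p(a -> b) - p(b -> a)`, clipped to `[0, 2 * indel]`; the
#' diagonal is 0. States that frequently exchange are cheap to substitute;
#' states that never transition into each other cost the maximum `2 * indel`,
#' at which point a substitution is never cheaper than a delete + insert.
#' Pairs involving a state never observed as an origin get the maximum cost.
#'
#' @param trans A `ws_trate` from [estimate_transition_rates()].
#' @param indel Insertion/deletion cost, positive (default 1, the standard
#'   convention).
#' @return An object of class `ws_costs`: list with `indel` and `sub`
#'   (6x6 symmetric, zero diagonal).
#' @export
build_cost_model <- function(trans, indel = 1) {
  if (!inherits(trans, "ws_trate")) {
    stop("`trans` must come from estimate_transition_rates()", call. = FALSE)
  }
  if (!is.numeric(indel) || indel <= 0) {
    stop("indel cost must be a positive number", call. = FALSE)
  }
  p <- trans$rates
  sub <- 2 * indel - p - t(p)
  sub[trans$unobserved, ] <- 2 * indel
  sub[, trans$unobserved] <- 2 * indel
  sub <- pmin(pmax(sub, 0), 2 * indel)
  diag(sub) <- 0
  sub <- (sub + t(sub)) / 2  # enforce exact symmetry
  dimnames(sub) <- list(.WS_STATES, .WS_STATES)
  structure(list(indel = indel, sub = sub), class = "ws_costs")
}

#' @export
print.ws_costs <- function(x, ...) {
  cat("<ws_costs> indel =", x$indel, "\n")
  print(round(x$sub, 3))
  invisible(x)
}

#' Optimal-matching distance between two state sequences
#'
#' Minimum total cost over all edit scripts (insertions and deletions at the
#' indel cost, substitutions at the model's cost) transforming `x` into `y`,
#' computed by the standard Needleman-Wunsch dynamic program
#' `D(i, j) = min(D(i-1, j) + indel, D(i, j-1) + indel,
#' D(i-1, j-1) + sub(x_i, y_j))`. Sequences may have different lengths.
#'
#' @param x,y Character vectors of state codes (possibly empty).
#' @param costs A `ws_costs` from [build_cost_model()].
#' @return A nonnegative number; 0 iff `x` and `y` are identical.
#' @examples
#' tr <- estimate_transition_rates(matrix(c("ST","ST","NW","NW",
#'                                          "ST","NW","NW","ST"), 2, 4, TRUE))
#' cm <- build_cost_model(tr)
#' om_distance(c("ST","ST"), c("ST","NW"), cm)
#' @export
om_distance <- function(x, y, costs) {
  stopifnot(inherits(costs, "ws_costs"))
  xi <- if (length(x)) state_index(x) else integer(0)
  yi <- if (length(y)) state_index(y) else integer(0)
  om_dist_cpp(xi, yi, costs$sub, costs$indel)
}

#' Pairwise optimal-matching distance matrix
#'
#' Computes [om_distance()] once per unordered pair of sequences; the result
#' is symmetric with a zero diagonal and satisfies the triangle inequality
#' (edit scripts compose).
#'
#' @param sequences Wide sequence tibble from [encode_sequences()] (or a
#'   character state matrix with person ids as row names).
#' @param costs A `ws_costs`.
#' @return A symmetric numeric matrix with person ids as dimnames, class
#'   `ws_distmat`.
#' @export
pairwise_distances <- function(sequences, costs) {
  stopifnot(inherits(costs, "ws_costs"))
  m <- as_state_matrix(sequences)
  if (nrow(m) < 2) stop("need at least 2 sequences", call. = FALSE)
  im <- matrix(state_index(as.vector(m)), nrow = nrow(m))
  D <- om_pairwise_cpp(im, costs$sub, costs$indel)
  dimnames(D) <- list(rownames(m), rownames(m))
  class(D) <- c("ws_distmat", class(D))
  D
}

# Coerce a wide sequence tibble or character matrix to a state matrix with
# person ids as rownames.
as_state_matrix <- function(sequences) {
  if (is.matrix(sequences)) {
    m <- sequences
    if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
    return(m)
  }
  m <- as.matrix(sequences[seq_cols()])
  rownames(m) <- as.character(sequences$person_id)
  m
}

#' Write / read a distance matrix as delimited text
#'
#' The square matrix is written with an id header row and id first column,
#' at full double precision (17 significant digits), so that a write/read
#' round trip is bit-identical.
#'
#' @param D Distance matrix with id dimnames.
#' @param path File path.
#' @return `write_distance_matrix()` returns `path` invisibly;
#'   `read_distance_matrix()` returns the matrix (class `ws_distmat`).
#' @export
write_distance_matrix <- function(D, path) {
  ids <- rownames(D)
  header <- paste(c("id", ids), collapse = ",")
  body <- vapply(seq_len(nrow(D)), function(i) {
    paste(c(ids[i], sprintf("%.17g", D[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path)
  ids <- strsplit(lines[1], ",", fixed = TRUE)[[1]][-1]
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    parts <- strsplit(lines[i + 1], ",", fixed = TRUE)[[1]]
    D[i, ] <- as.numeric(parts[-1])
  }
  class(D) <- c("ws_distmat", class(D))
  D
}
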