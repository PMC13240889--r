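# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths (recursive enumeration instead of the
# iterative DP; coordinate geometry instead of distance-based identities).

# Brute-force edit distance: recursively enumerate edit scripts (delete,
# insert, substitute/match on the first elements) and take the cheapest.
bf_edit_distance <- function(x, y, sub, indel) {
  if (length(x) == 0) return(length(y) * indel)
  if (length(y) == 0) return(length(x) * indel)
  min(
    bf_edit_distance(x[-1], y, sub, indel) + indel,
    bf_edit_distance(x, y[-1], sub, indel) + indel,
    bf_edit_distance(x[-1], y[-1], sub, indel) + sub[x[1], y[1]]
  )
}

# Coordinate-based within-cluster sum of squares (deviation from centroid).
coord_within_ss <- function(pts, members) {
  p <- pts[members, , drop = FALSE]
  ctr <- colMeans(p)
  sum(sweep(p, 2, ctr)^2)
}

# Coordinate-based Calinski-Harabasz pseudo-F.
coord_ch <- function(pts, labels) {
  n <- nrow(pts)
  k <- length(unique(labels))
  total <- coord_within_ss(pts, seq_len(n))
  W <- sum(vapply(split(seq_len(n), labels),
                  function(idx) coord_within_ss(pts, idx), numeric(1)))
  ((total - W) / (k - 1)) / (W / (n - k))
}

# Greedy Ward agglomeration on coordinates: at each step merge the pair of
# clusters with the smallest increase in total within-SS; returns the sorted
# sequence of SS increments.
coord_ward_heights <- function(pts) {
  clusters <- as.list(seq_len(nrow(pts)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        a <- clusters[[i]]; b <- clusters[[j]]
        dss <- coord_within_ss(pts, c(a, b)) -
          coord_within_ss(pts, a) - coord_within_ss(pts, b)
        if (dss < best_d) { best_d <- dss; best <- c(j, i) }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    clusters[[best[1]]] <- merged
    heights <- c(heights, best_d)
  }
  heights
}

# Wide sequence tibble from a list of state-code vectors (length 10 each).
make_seqs <- function(...) {
  vecs <- list(...)
  if (length(vecs) == 1 && is.list(vecs[[1]]) && !is.character(vecs[[1]])) {
    vecs <- vecs[[1]]
  }
  m <- do.call(rbind, vecs)
  out <- tibble::tibble(person_id = sprintf("P%03d", seq_len(nrow(m))))
  for (p in 1:10) out[[paste0("p", p)]] <- m[, p]
  out
}

# Long panel for one person from a state vector (ages start..start+9).
panel_from_states <- function(states, person_id = "A", start = 25,
                              hours = NULL, occupation = NULL) {
  n <- length(states)
  tibble::tibble(
    person_id = person_id, age = start + seq_len(n) - 1L,
    state = states,
    weekly_hours = if (is.null(hours)) ifelse(states == "NW", 0, 40) else hours,
    occupation = if (is.null(occupation)) {
      ifelse(states == "NW", NA_character_, "clerical")
    } else occupation,
    observed = !is.na(states)
  )
}

# Distance matrix of points on a line (the Euclidean fixture).
line_dist <- function(x) {
  D <- abs(outer(x, x, "-"))
  dimnames(D) <- list(paste0("S", seq_along(x)), paste0("S", seq_along(x)))
  D
}
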