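#' Ward hierarchical agglomeration on a distance matrix
#'
#' Runs Ward's minimum-variance agglomeration under the squared-dissimilarity
#' convention (`ward.D2`), the standard choice when only pairwise
#' dissimilarities — not coordinates — are available, as with
#' optimal-matching distances. Each merge height is recorded as the increase
#' in total within-cluster sum of squares implied by the squared-distance
#' decomposition (`height_ss = h^2 / 2` where `h` is the `ward.D2` fusion
#' level).
#'
#' @param D Symmetric nonnegative distance matrix (e.g. from
#'   [pairwise_distances()]).
#' @return An object of class `ws_dendrogram`: list with the underlying
#'   `hclust` tree, a `merges` tibble (step, left, right, height_ss, size;
#'   negative node = leaf index, positive = earlier merge), and `ids`.
#' @export
ward_linkage <- function(D) {
  D <- unclass(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("D must be a square matrix", call. = FALSE)
  }
  if (nrow(D) < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(D < 0)) stop("distances must be nonnegative", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-9) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (is.null(rownames(D))) {
    dimnames(D) <- list(paste0("S", seq_len(nrow(D))),
                        paste0("S", seq_len(nrow(D))))
  }
  hc <- hclust(as.dist(D), method = "ward.D2")
  sizes <- integer(length(hc$height))
  size_of <- function(node, step) {
    if (node < 0) 1L else sizes[node]
  }
  for (s in seq_along(hc$height)) {
    sizes[s] <- size_of(hc$merge[s, 1]) + size_of(hc$merge[s, 2])
  }
  merges <- tibble::tibble(
    step = seq_along(hc$height),
    left = hc$merge[, 1], right = hc$merge[, 2],
    height_ss = hc$height^2 / 2,
    size = sizes
  )
  structure(list(hclust = hc, merges = merges, ids = rownames(D)),
            class = "ws_dendrogram")
}

#' @export
print.ws_dendrogram <- function(x, ...) {
  cat("<ws_dendrogram> Ward tree over", length(x$ids), "sequences\n")
  invisible(x)
}

#' Distance-based within-cluster sum of squares
#'
#' `SS(C) = (1 / |C|) * sum_{i < j in C} d(i, j)^2`. For Euclidean distances
#' this equals the sum of squared deviations from the cluster centroid, which
#' is what makes Ward heights and the stopping indices computable from a
#' distance matrix alone.
#'
#' @param D Distance matrix.
#' @param members Integer or character index vector of cluster members.
#' @return A nonnegative number (0 for singletons).
#' @export
within_ss <- function(D, members) {
  if (length(members) == 0) stop("empty member set", call. = FALSE)
  sub <- unclass(D)[members, members, drop = FALSE]
  sum(sub^2) / (2 * nrow(sub))
}

#' Calinski-Harabasz pseudo-F for a partition
#'
#' `CH = ((T - W) / (k - 1)) / (W / (n - k))` with `W` the summed
#' within-cluster SS and `T` the total SS, both computed from distances via
#' [within_ss()]. Larger is better. A perfectly separated partition of
#' duplicated points has `W = 0` and returns `Inf`.
#'
#' @param D Distance matrix.
#' @param labels Cluster label per observation.
#' @param k Number of clusters (must match `labels` and satisfy 1 < k < n).
#' @return A nonnegative number (possibly `Inf`).
#' @export
calinski_harabasz <- function(D, labels, k = length(unique(labels))) {
  n <- nrow(unclass(D))
  if (k <= 1 || k >= n) {
    stop("k must satisfy 1 < k < n", call. = FALSE)
  }
  if (length(labels) != n) {
    stop("labels length must match distance matrix", call. = FALSE)
  }
  total <- within_ss(D, seq_len(n))
  W <- sum(vapply(split(seq_len(n), labels), function(idx) within_ss(D, idx),
                  numeric(1)))
  if (W == 0) return(Inf)
  ((total - W) / (k - 1)) / (W / (n - k))
}

#' Duda-Hart index for one cluster split
#'
#' `Je(2)/Je(1)`: the ratio of the within-SS after splitting a parent cluster
#' into two children over the within-SS of the unsplit parent, with the
#' associated pseudo-T-squared
#' `(Je(1) - Je(2)) / (Je(2) / (n_a + n_b - 2))`. The ratio lies in \[0, 1\];
#' values near 1 mean the split buys little. A zero-SS parent is degenerate:
#' ratio 1, pseudo-T2 0.
#'
#' @param D Distance matrix.
#' @param parent_members Indices of the parent cluster.
#' @param child_a,child_b Disjoint index sets partitioning the parent.
#' @return List with `ratio` and `pseudo_t2`.
#' @export
duda_hart <- function(D, parent_members, child_a, child_b) {
  if (length(intersect(child_a, child_b)) > 0 ||
      !setequal(union(child_a, child_b), parent_members) ||
      length(child_a) == 0 || length(child_b) == 0) {
    stop("children must be a disjoint nonempty partition of the parent",
         call. = FALSE)
  }
  je1 <- within_ss(D, parent_members)
  je2 <- within_ss(D, child_a) + within_ss(D, child_b)
  if (je1 == 0) return(list(ratio = 1, pseudo_t2 = 0))
  ratio <- je2 / je1
  m <- length(child_a) + length(child_b)
  pseudo_t2 <- if (je2 == 0) Inf else (je1 - je2) / (je2 / (m - 2))
  list(ratio = ratio, pseudo_t2 = pseudo_t2)
}

#' Choose the number of clusters by stopping indices
#'
#' Cuts the Ward tree at each candidate `k`, computes the Calinski-Harabasz
#' pseudo-F of the cut and the Duda-Hart ratio / pseudo-T2 of the split that
#' refines cut `k` into cut `k + 1`, and selects the `k` maximizing CH. Ties
#' are broken by the larger Duda-Hart ratio, then by the smaller `k`. Pass
#' `force_k` to override the indices with a substantive ("conceptual
#' relevance") choice; the full diagnostics table is always retained.
#'
#' @param dendrogram A `ws_dendrogram` from [ward_linkage()].
#' @param D The distance matrix the tree was built on.
#' @param k_range Candidate cluster counts (default 4:8).
#' @param force_k Optional explicit `k` overriding the index-based choice.
#' @return An object of class `ws_clusters`: list with `k`, `labels` (named
#'   integer vector covering 1..k), `diagnostics` (tibble: k, ch, dh_ratio,
#'   dh_pseudo_t2), `rationale`, `dendrogram`, `ids`.
#' @export
select_k <- function(dendrogram, D, k_range = 4:8, force_k = NULL) {
  stopifnot(inherits(dendrogram, "ws_dendrogram"))
  n <- length(dendrogram$ids)
  if (!is.null(force_k)) {
    if (force_k < 2 || force_k > n - 1) {
      stop("force_k must lie in [2, n - 1]", call. = FALSE)
    }
    k_range <- unique(c(force_k, k_range))
  }
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0) stop("empty k_range", call. = FALSE)
  if (min(k_range) < 2 || max(k_range) > n - 1) {
    stop("k_range must lie within [2, n - 1]", call. = FALSE)
  }
  hc <- dendrogram$hclust
  diag_tbl <- purrr::map_dfr(k_range, function(k) {
    labels <- cutree(hc, k = k)
    ch <- calinski_harabasz(D, labels, k)
    dh <- cut_duda_hart(hc, D, k)
    tibble::tibble(k = k, ch = ch, dh_ratio = dh$ratio,
                   dh_pseudo_t2 = dh$pseudo_t2)
  })
  if (!is.null(force_k)) {
    k_star <- as.integer(force_k)
    rationale <- "forced"
  } else {
    ord <- order(-diag_tbl$ch, -diag_tbl$dh_ratio, diag_tbl$k)
    k_star <- diag_tbl$k[ord[1]]
    rationale <- "max Calinski-Harabasz"
  }
  labels <- cutree(hc, k = k_star)
  names(labels) <- dendrogram$ids
  structure(list(k = k_star, labels = labels, diagnostics = diag_tbl,
                 rationale = rationale, dendrogram = dendrogram,
                 ids = dendrogram$ids),
            class = "ws_clusters")
}

# Duda-Hart statistics for the split that turns the k-cluster cut into the
# (k+1)-cluster cut (Stata `cluster stop, rule(duda)` convention).
cut_duda_hart <- function(hc, D, k) {
  n <- length(hc$order)
  if (k + 1 > n) return(list(ratio = NA_real_, pseudo_t2 = NA_real_))
  lab_k <- cutree(hc, k = k)
  lab_k1 <- cutree(hc, k = k + 1)
  # the parent is the k-cut cluster containing two (k+1)-cut clusters
  split_tab <- table(lab_k, lab_k1)
  parent_lab <- which(rowSums(split_tab > 0) == 2)[1]
  parent <- which(lab_k == parent_lab)
  kids <- split(parent, lab_k1[parent])
  duda_hart(D, parent, kids[[1]], kids[[2]])
}

#' @export
print.ws_clusters <- function(x, ...) {
  cat("<ws_clusters> k =", x$k, "over", length(x$labels),
      "sequences (", x$rationale, ")\n")
  print(x$diagnostics)
  invisible(x)
}

#' @rdname select_k
#' @param x A `ws_clusters` object.
#' @param ... Unused.
#' @export
tidy.ws_clusters <- function(x, ...) {
  tibble::tibble(person_id = names(x$labels),
                 cluster = unname(x$labels))
}

#' @rdname select_k
#' @export
glance.ws_clusters <- function(x, ...) {
  row <- x$diagnostics[x$diagnostics$k == x$k, ]
  tibble::tibble(k = x$k, n = length(x$labels), ch = row$ch,
                 dh_ratio = row$dh_ratio, rationale = x$rationale)
}

#' Diagnostics plot for a cluster solution
#'
#' Calinski-Harabasz pseudo-F against the candidate number of clusters, with
#' the selected `k` highlighted.
#'
#' @param object A `ws_clusters` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ws_clusters <- function(object, ...) {
  d <- object$diagnostics
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$ch)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters k",
                  y = "Calinski-Harabasz pseudo-F",
                  title = paste0("Cluster-count diagnostics (chosen k = ",
                                 object$k, ")")) +
    ggplot2::theme_minimal()
}
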