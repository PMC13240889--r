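#' Profile trajectory clusters
#'
#' Describes each cluster by direct tabulation: size and sample share,
#' overall person-year share per state, the 10x6 per-position state
#' frequency distribution (the data behind sequence-distribution plots),
#' the mean number of adjacent-position state changes per person, a
#' deterministic text label (see [label_cluster()]), and covariate
#' distributions within the cluster.
#'
#' @param solution A `ws_clusters` from [select_k()].
#' @param sequences The wide sequence tibble the solution was fit on.
#' @param covariates Optional person-level covariate tibble (complete-case).
#' @param thresholds Label thresholds passed to [label_cluster()].
#' @return A list of `ws_profile` objects (one per cluster), of class
#'   `ws_profiles`.
#' @export
profile_clusters <- function(solution, sequences, covariates = NULL,
                             thresholds = label_thresholds()) {
  stopifnot(inherits(solution, "ws_clusters"))
  m <- as_state_matrix(sequences)
  if (!setequal(rownames(m), names(solution$labels))) {
    stop("cluster labels and sequence ids do not match", call. = FALSE)
  }
  m <- m[names(solution$labels), , drop = FALSE]
  n <- nrow(m)
  profiles <- lapply(sort(unique(solution$labels)), function(cl) {
    idx <- which(solution$labels == cl)
    sub <- m[idx, , drop = FALSE]
    pos_dist <- t(vapply(seq_len(ncol(sub)), function(p) {
      tabulate(state_index(sub[, p]), nbins = 6) / nrow(sub)
    }, numeric(6)))
    colnames(pos_dist) <- .WS_STATES
    rownames(pos_dist) <- seq_cols()
    state_share <- colSums(pos_dist) / ncol(sub)
    transitions <- apply(sub, 1, function(s) sum(s[-1] != s[-length(s)]))
    cov_summary <- NULL
    if (!is.null(covariates)) {
      cov_sub <- covariates[covariates$person_id %in% names(idx), , drop = FALSE]
      cov_cols <- setdiff(names(cov_sub), "person_id")
      cov_summary <- purrr::map_dfr(cov_cols, function(cc) {
        x <- cov_sub[[cc]]
        if (is.numeric(x) && length(unique(x)) > 2) {
          tibble::tibble(covariate = cc, level = "mean",
                         value = mean(x, na.rm = TRUE))
        } else {
          tab <- table(x, useNA = "no")
          tibble::tibble(covariate = cc, level = names(tab),
                         value = as.numeric(tab) / sum(tab))
        }
      })
    }
    prof <- structure(list(
      cluster = cl, size = length(idx), share = length(idx) / n,
      state_share = state_share, position_distribution = pos_dist,
      mean_transitions = mean(transitions), covariate_summary = cov_summary,
      person_ids = names(idx)
    ), class = "ws_profile")
    prof$label <- label_cluster(prof, thresholds)
    prof
  })
  structure(profiles, class = "ws_profiles")
}

#' @export
print.ws_profile <- function(x, ...) {
  cat("<ws_profile> cluster", x$cluster, "(", x$size, "persons,",
      sprintf("%.1f%%", 100 * x$share), ") label:", x$label, "\n")
  cat("  state shares:",
      paste(sprintf("%s %.2f", names(x$state_share), x$state_share),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.ws_profiles <- function(x, ...) {
  for (p in x) print(p)
  invisible(x)
}

#' Label thresholds for [label_cluster()]
#'
#' All thresholds are reproducible stand-ins for the by-inspection labels
#' used in descriptive trajectory tables; each is configurable.
#'
#' @param only Dominance share for "`X` only" (default 0.90).
#' @param mainly Dominance share for "mainly `X`" (default 0.60).
#' @param pair Minimum share for each of the top two states in "`X` + `Y`"
#'   (default 0.25).
#' @param volatile Mean transitions per person for "volatile" (default 3).
#' @param missing_tail `MIS` share triggering the "to missing" suffix when
#'   concentrated at the window end (default 0.20).
#' @return A named list.
#' @export
label_thresholds <- function(only = 0.90, mainly = 0.60, pair = 0.25,
                             volatile = 3, missing_tail = 0.20) {
  list(only = only, mainly = mainly, pair = pair, volatile = volatile,
       missing_tail = missing_tail)
}

#' Deterministic heuristic label for a cluster profile
#'
#' Ordered rules on the non-`MIS` state shares: "`X` only" when a state holds
#' at least 90% of person-years; "mainly `X`" at 60%; "`X` + `Y`" when the top
#' two states each hold at least 25%; "volatile" when the mean number of
#' year-to-year state changes is at least 3; otherwise "mixed". When the
#' `MIS` share reaches 20% and at least half of the `MIS` mass sits in the
#' last three window positions (trailing panel attrition), " to missing" is
#' appended.
#'
#' @param profile A `ws_profile`.
#' @param thresholds See [label_thresholds()].
#' @return A character label.
#' @export
label_cluster <- function(profile, thresholds = label_thresholds()) {
  sh <- profile$state_share
  work <- sort(sh[names(sh) != "MIS"], decreasing = TRUE)
  base <- if (work[1] >= thresholds$only) {
    paste(names(work)[1], "only")
  } else if (work[1] >= thresholds$mainly) {
    paste("mainly", names(work)[1])
  } else if (length(work) >= 2 && work[1] >= thresholds$pair &&
             work[2] >= thresholds$pair) {
    paste(names(work)[1], "+", names(work)[2])
  } else if (profile$mean_transitions >= thresholds$volatile) {
    "volatile"
  } else {
    "mixed"
  }
  mis_by_pos <- profile$position_distribution[, "MIS"]
  mis_total <- sum(mis_by_pos)
  if (sh[["MIS"]] >= thresholds$missing_tail && mis_total > 0 &&
      sum(mis_by_pos[8:10]) >= 0.5 * mis_total) {
    base <- paste(base, "to missing")
  }
  base
}

#' Modal sequence of a cluster
#'
#' The per-position most frequent state; ties broken by alphabet order
#' (`NW < ST < EVE < NGT < ONS < MIS`).
#'
#' @param profile A `ws_profile`.
#' @return A length-10 character vector of state codes.
#' @export
modal_sequence <- function(profile) {
  apply(profile$position_distribution, 1, function(row) {
    .WS_STATES[which.max(row)]  # which.max takes the first (alphabet-order) tie
  })
}

#' Long-format plot data for cluster profiles
#'
#' One row per (cluster, position, state) with the state frequency — the
#' machine-readable data behind sequence-distribution plots, usable by any
#' plotting front end.
#'
#' @param profiles A `ws_profiles` object.
#' @return A tibble with columns cluster, label, position, state, frequency.
#' @export
profile_plot_data <- function(profiles) {
  purrr::map_dfr(profiles, function(p) {
    pd <- p$position_distribution
    tibble::tibble(
      cluster = p$cluster, label = p$label,
      position = rep(seq_len(nrow(pd)), times = ncol(pd)),
      state = rep(colnames(pd), each = nrow(pd)),
      frequency = as.vector(pd)
    )
  })
}

#' @rdname profile_clusters
#' @param x A `ws_profiles` object.
#' @param ... Unused.
#' @export
tidy.ws_profiles <- function(x, ...) {
  purrr::map_dfr(x, function(p) {
    tibble::tibble(cluster = p$cluster, label = p$label, size = p$size,
                   share = p$share, mean_transitions = p$mean_transitions,
                   modal = paste(modal_sequence(p), collapse = "-"))
  })
}

#' Sequence state-distribution plot
#'
#' Stacked per-position state frequencies by cluster — the standard
#' descriptive display for trajectory clusters.
#'
#' @param object A `ws_profiles` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ws_profiles <- function(object, ...) {
  d <- profile_plot_data(object)
  d$state <- factor(d$state, levels = .WS_STATES)
  d$panel_lab <- paste0(d$cluster, ": ", d$label)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$frequency,
                                  fill = .data$state)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~panel_lab) +
    ggplot2::scale_x_continuous(breaks = c(1, 4, 7, 10)) +
    ggplot2::labs(x = "window position (year)", y = "state frequency",
                  fill = "state") +
    ggplot2::theme_minimal()
}
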