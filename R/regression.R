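#' Specify a cluster-outcome regression model
#'
#' Declares the outcome, family, cluster exposure with its reference
#' category (conventionally the "mainly ST" cluster), adjustment covariates,
#' and an optional interaction factor (gender).
#'
#' @param outcome Outcome column name.
#' @param family `"linear"` (OLS, for standardized continuous outcomes) or
#'   `"logistic"` (binary outcomes, maximum likelihood via IRLS).
#' @param exposure Column holding cluster membership (default `"cluster"`).
#' @param reference Reference exposure level (required; for trajectory
#'   clusters this is the mainly-ST cluster).
#' @param covariates Character vector of adjustment terms.
#' @param interaction Optional column name for an interaction factor.
#' @param standardized Is the outcome on the mean-50/SD-10 scale, so that
#'   estimates read as tenths of an SD? Default `TRUE` for linear models.
#' @return A list of class `ws_model_spec`.
#' @export
model_spec <- function(outcome, family = c("linear", "logistic"),
                       exposure = "cluster", reference,
                       covariates = character(), interaction = NULL,
                       standardized = NULL) {
  family <- match.arg(family)
  if (missing(reference) || is.null(reference)) {
    stop("a reference exposure level must be declared", call. = FALSE)
  }
  if (is.null(standardized)) standardized <- family == "linear"
  structure(list(outcome = outcome, family = family, exposure = exposure,
                 reference = as.character(reference),
                 covariates = covariates, interaction = interaction,
                 standardized = standardized),
            class = "ws_model_spec")
}

prepare_model_frame <- function(spec, data, with_interaction = FALSE) {
  needed <- c(spec$outcome, spec$exposure, spec$covariates,
              if (with_interaction) spec$interaction)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(data[needed])
  df <- df[complete.cases(df), , drop = FALSE]  # listwise deletion
  expo <- factor(df[[spec$exposure]])
  if (!spec$reference %in% levels(expo)) {
    stop("reference level '", spec$reference, "' not found in exposure '",
         spec$exposure, "'", call. = FALSE)
  }
  df[[spec$exposure]] <- stats::relevel(expo, ref = spec$reference)
  for (cc in spec$covariates) {
    if (is.character(df[[cc]])) df[[cc]] <- factor(df[[cc]])
  }
  df
}

build_formula <- function(spec, with_interaction = FALSE) {
  rhs <- c(if (with_interaction) {
    paste0("`", spec$exposure, "` * `", spec$interaction, "`")
  } else {
    paste0("`", spec$exposure, "`")
  }, if (length(spec$covariates) > 0) paste0("`", spec$covariates, "`"))
  stats::as.formula(paste0("`", spec$outcome, "` ~ ",
                           paste(rhs, collapse = " + ")))
}

effect_table <- function(coefs, ses, n, spec, df_resid = NULL) {
  stat <- coefs / ses
  p <- if (!is.null(df_resid)) {
    2 * pt(abs(stat), df_resid, lower.tail = FALSE)
  } else {
    2 * pnorm(abs(stat), lower.tail = FALSE)
  }
  out <- tibble::tibble(term = names(coefs), estimate = unname(coefs),
                        std.error = unname(ses), statistic = unname(stat),
                        p.value = unname(p), n = n)
  if (spec$family == "linear" && isTRUE(spec$standardized)) {
    out$effect_size_sd <- out$estimate / 10
  }
  out
}

new_ws_fit <- function(model, spec, table, extra = list()) {
  structure(c(list(model = model, spec = spec, table = table), extra),
            class = "ws_fit")
}

#' Ordinary least squares fit of a cluster-outcome association
#'
#' Reference-cell coded OLS of a continuous (usually standardized) outcome
#' on cluster membership and covariates, with conventional homoskedastic
#' standard errors by default and an HC1 heteroskedasticity-robust option.
#' On a mean-50/SD-10 outcome a one-point estimate is one tenth of an SD.
#'
#' @param spec A [model_spec()] with `family = "linear"`.
#' @param data Analysis tibble (one row per person).
#' @param robust Use HC1 robust standard errors (requires the sandwich
#'   package)? Default `FALSE`.
#' @return A `ws_fit`; `tidy()` gives the effect table (term, estimate,
#'   std.error, statistic, p.value, n, effect_size_sd).
#' @export
fit_linear <- function(spec, data, robust = FALSE) {
  stopifnot(inherits(spec, "ws_model_spec"), spec$family == "linear")
  df <- prepare_model_frame(spec, data)
  fit <- lm(build_formula(spec), data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; collinear term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  V <- if (robust) {
    if (!requireNamespace("sandwich", quietly = TRUE)) {
      stop("robust standard errors require the sandwich package",
           call. = FALSE)
    }
    sandwich::vcovHC(fit, type = "HC1")
  } else {
    vcov(fit)
  }
  tbl <- effect_table(cf, sqrt(diag(V)), nrow(df), spec,
                      df_resid = fit$df.residual)
  new_ws_fit(fit, spec, tbl)
}

#' Logistic regression fit of a cluster-outcome association
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, convergence tolerance 1e-10, Wald standard errors from the
#' observed information). Degenerate outcomes (all 0 or all 1) and perfect
#' separation raise errors instead of returning silently divergent
#' estimates.
#'
#' @param spec A [model_spec()] with `family = "logistic"`.
#' @param data Analysis tibble with a 0/1 outcome.
#' @return A `ws_fit`; estimates are log odds ratios versus the reference
#'   cluster.
#' @export
fit_logistic <- function(spec, data) {
  stopifnot(inherits(spec, "ws_model_spec"), spec$family == "logistic")
  df <- prepare_model_frame(spec, data)
  y <- df[[spec$outcome]]
  if (!all(y %in% c(0, 1))) {
    stop("logistic outcome must be coded 0/1", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("degenerate outcome: all responses are ", y[1],
         "; the likelihood has no interior maximum", call. = FALSE)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(build_formula(spec), data = df, family = binomial(),
        control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separation || any(abs(coef(fit)) > 15)) {
    stop("(quasi-)perfect separation detected: some covariate pattern ",
         "predicts the outcome exactly; coefficients diverge", call. = FALSE)
  }
  if (!fit$converged) {
    stop("IRLS did not converge after ", fit$iter, " iterations (deviance ",
         format(fit$deviance), ")", call. = FALSE)
  }
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; collinear term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  tbl <- effect_table(cf, sqrt(diag(vcov(fit))), nrow(df), spec)
  new_ws_fit(fit, spec, tbl)
}

#' Cluster-by-gender interaction analysis
#'
#' Refits the model with cluster x gender product terms and reports every
#' interaction estimate plus the count significant at the 5% level. No
#' multiplicity correction is applied — with many interaction terms a
#' non-trivial share of "significant" ones is expected by chance, which the
#' attached note restates.
#'
#' @param spec A [model_spec()] with a non-`NULL` `interaction` field.
#' @param data Analysis tibble.
#' @param alpha Two-sided significance level for the count (default 0.05).
#' @return A `ws_fit` with extra fields `interaction_terms`,
#'   `n_interactions`, `n_significant`, `note`.
#' @export
fit_gender_interaction <- function(spec, data, alpha = 0.05) {
  stopifnot(inherits(spec, "ws_model_spec"))
  if (is.null(spec$interaction)) {
    stop("spec declares no interaction factor", call. = FALSE)
  }
  df <- prepare_model_frame(spec, data, with_interaction = TRUE)
  g <- df[[spec$interaction]]
  if (length(unique(g)) < 2) {
    stop("interaction factor '", spec$interaction,
         "' is constant in the analysis sample", call. = FALSE)
  }
  fit <- if (spec$family == "linear") {
    lm(build_formula(spec, with_interaction = TRUE), data = df)
  } else {
    glm(build_formula(spec, with_interaction = TRUE), data = df,
        family = binomial(),
        control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  }
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient interaction design; collinear term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  df_resid <- if (spec$family == "linear") fit$df.residual else NULL
  tbl <- effect_table(cf, sqrt(diag(vcov(fit))), nrow(df), spec, df_resid)
  is_inter <- grepl(":", tbl$term, fixed = TRUE)
  n_sig <- sum(tbl$p.value[is_inter] < alpha)
  note <- paste0(n_sig, " of ", sum(is_inter), " interaction terms ",
                 "significant at alpha = ", alpha, "; with no multiplicity ",
                 "correction some significant terms are expected by chance")
  new_ws_fit(fit, spec, tbl,
             extra = list(interaction_terms = tbl$term[is_inter],
                          n_interactions = sum(is_inter),
                          n_significant = n_sig, note = note))
}

#' @export
print.ws_fit <- function(x, ...) {
  cat("<ws_fit>", x$spec$family, "model:", x$spec$outcome, "~",
      x$spec$exposure, "(ref:", paste0(x$spec$reference, ")"), "\n")
  print(x$table)
  if (!is.null(x$note)) cat(x$note, "\n")
  invisible(x)
}

#' @rdname fit_linear
#' @param x A `ws_fit` object.
#' @param ... Unused.
#' @export
tidy.ws_fit <- function(x, ...) x$table

#' @rdname fit_linear
#' @export
glance.ws_fit <- function(x, ...) {
  if (x$spec$family == "linear") {
    s <- summary(x$model)
    tibble::tibble(family = "linear", n = x$table$n[1],
                   r.squared = s$r.squared, sigma = s$sigma)
  } else {
    tibble::tibble(family = "logistic", n = x$table$n[1],
                   deviance = x$model$deviance,
                   null.deviance = x$model$null.deviance,
                   converged = x$model$converged)
  }
}

#' Coefficient plot for a fitted model
#'
#' Point estimates with 95% Wald intervals for the non-intercept terms.
#'
#' @param object A `ws_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ws_fit <- function(object, ...) {
  d <- object$table[object$table$term != "(Intercept)", ]
  d$lo <- d$estimate - 1.96 * d$std.error
  d$hi <- d$estimate + 1.96 * d$std.error
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::labs(
      x = if (object$spec$family == "linear") "estimate (points)"
          else "log odds ratio",
      y = NULL,
      title = paste(object$spec$outcome, "~", object$spec$exposure)) +
    ggplot2::theme_minimal()
}

#' Summary cells in the significant-effects display convention
#'
#' Rounds significant point estimates on standardized linear outcomes to
#' integer points (read as tenths of an SD; negative = worse function) and
#' reports significant logistic terms as "+" / "-" direction symbols.
#' Non-significant cells are blank, mirroring tables that display only
#' significant associations.
#'
#' @param effects A `ws_fit` or its `tidy()` effect table.
#' @param alpha Two-sided significance level (default 0.05).
#' @param family `"linear"` or `"logistic"`; inferred from a `ws_fit`.
#' @return Tibble with columns term, estimate, p.value, cell.
#' @export
effect_size_report <- function(effects, alpha = 0.05, family = NULL) {
  if (inherits(effects, "ws_fit")) {
    family <- effects$spec$family
    effects <- effects$table
  }
  if (is.null(family)) {
    family <- if ("effect_size_sd" %in% names(effects)) "linear" else "logistic"
  }
  cell <- vapply(seq_len(nrow(effects)), function(i) {
    if (effects$term[i] == "(Intercept)") return("")
    if (effects$p.value[i] >= alpha) return("")
    if (family == "linear") {
      sprintf("%+d", as.integer(round(effects$estimate[i])))
    } else {
      if (effects$estimate[i] > 0) "+" else "-"
    }
  }, character(1))
  tibble::tibble(term = effects$term, estimate = effects$estimate,
                 p.value = effects$p.value, cell = cell)
}
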