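# Three-parameter logistic dose-response analysis.
#
# Model: response = bottom + (top - bottom) / (1 + 10^(logEC50 - x)),
# x = log10 molar concentration, Hill slope fixed at 1.

logistic3 <- function(x, bottom, top, logec50) {
  bottom + (top - bottom) / (1 + 10^(logec50 - x))
}

# multi-start nonlinear least squares for the 3PL model.
# Returns list(par, ss, converged, vcov); never throws on fit failure.
fit_3pl_engine <- function(x, y, n_starts = 5) {
  xr <- range(x)
  grid <- seq(xr[1], xr[2], length.out = n_starts)
  mean_by_x <- tapply(y, x, mean)
  b0 <- min(mean_by_x)
  t0 <- max(mean_by_x)
  if (t0 == b0) t0 <- b0 + max(1e-8, abs(b0) * 1e-6)
  best <- NULL
  dat <- data.frame(x = x, y = y)
  for (g in grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(logec50 - x)),
        data = dat,
        start = list(bottom = b0, top = t0, logec50 = g),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(stats::resid(fit)^2)
    if (is.null(best) || ss < best$ss - 1e-12) {
      vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
      best <- list(par = stats::coef(fit), ss = ss, converged = TRUE,
                   vcov = vc)
    }
  }
  if (is.null(best)) {
    # fall back to a flat model so downstream code sees a flagged fit
    m <- mean(y)
    best <- list(par = c(bottom = m, top = m, logec50 = mean(xr)),
                 ss = sum((y - m)^2), converged = FALSE, vcov = NULL)
  }
  best
}

#' Fit a three-parameter logistic dose-response curve
#'
#' Least-squares fit of `bottom + (top - bottom) / (1 + 10^(logEC50 - x))`
#' with the Hill slope fixed at 1, using Levenberg-Marquardt iterations
#' started from a grid of logEC50 values spanning the tested concentration
#' range (bottom/top start at the data extremes). Parameter standard errors
#' come from the curvature at the optimum and 95% confidence intervals use
#' the t distribution with `n - 3` degrees of freedom.
#'
#' @param data Tibble with columns `log10_conc_M` (log10 molar) and
#'   `response`; replicate rows share a concentration. At least 4 distinct
#'   concentrations are required.
#' @param n_starts Number of logEC50 grid starts.
#' @return An `or_fit` object. Access parameters via [tidy()], fit summary
#'   via [glance()]; fields include `coefficients` (bottom, top, logec50),
#'   `se`, `ci_lower`/`ci_upper`, `ss`, `df`, `converged`, `degenerate`.
#'   A fit that fails to converge is flagged, not an error.
#' @export
fit_3pl <- function(data, n_starts = 5) {
  data <- tibble::as_tibble(data)
  if (!all(c("log10_conc_M", "response") %in% names(data))) {
    orevo_abort("data must have columns log10_conc_M and response",
                "orevo_dose_error")
  }
  x <- data$log10_conc_M
  y <- data$response
  if (length(unique(x)) < 4L) {
    orevo_abort("at least 4 distinct concentrations are required",
                "orevo_dose_error")
  }
  eng <- fit_3pl_engine(x, y, n_starts = n_starts)
  n <- length(y)
  df <- n - 3L
  se <- rep(NA_real_, 3)
  names(se) <- names(eng$par)
  if (!is.null(eng$vcov)) {
    d <- diag(eng$vcov)
    se <- sqrt(pmax(d, 0))
  }
  tcrit <- stats::qt(0.975, df)
  span <- unname(eng$par["top"] - eng$par["bottom"])
  scale_y <- max(abs(y), 1e-12)
  degenerate <- !eng$converged || is.na(se["logec50"]) ||
    abs(span) < 1e-6 * scale_y
  structure(
    list(coefficients = eng$par, se = se,
         ci_lower = eng$par - tcrit * se,
         ci_upper = eng$par + tcrit * se,
         span = span, ss = eng$ss, df = df, n = n,
         converged = eng$converged, degenerate = degenerate,
         data = tibble::tibble(log10_conc_M = x, response = y)),
    class = "or_fit")
}

#' @export
print.or_fit <- function(x, ...) {
  cat("<or_fit> 3-parameter logistic",
      if (!x$converged) "(NOT converged)" else if (x$degenerate) "(degenerate)",
      "\n")
  print(tidy(x))
  cat(sprintf("SS = %.4g on %d df\n", x$ss, x$df))
  invisible(x)
}

#' @method tidy or_fit
#' @export
tidy.or_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    conf.low = unname(x$ci_lower),
    conf.high = unname(x$ci_upper))
}

#' @method glance or_fit
#' @export
glance.or_fit <- function(x, ...) {
  tibble::tibble(
    logec50 = unname(x$coefficients["logec50"]),
    se_logec50 = unname(x$se["logec50"]),
    bottom = unname(x$coefficients["bottom"]),
    top = unname(x$coefficients["top"]),
    span = x$span,
    ss = x$ss, df = x$df, nobs = x$n,
    converged = x$converged, degenerate = x$degenerate)
}

#' Plot a fitted dose-response curve over the data
#'
#' @param object An `or_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot or_fit
#' @export
autoplot.or_fit <- function(object, ...) {
  xr <- range(object$data$log10_conc_M)
  curve <- tibble::tibble(
    log10_conc_M = seq(xr[1], xr[2], length.out = 200))
  curve$response <- logistic3(curve$log10_conc_M,
                              object$coefficients["bottom"],
                              object$coefficients["top"],
                              object$coefficients["logec50"])
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$log10_conc_M, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::labs(x = "log10 concentration (M)", y = "response") +
    ggplot2::theme_minimal()
}

#' Gate a dose-response fit as a true agonist response
#'
#' Applies the three agonist criteria: (1) the 95% confidence intervals of
#' the fitted top and bottom do not overlap; (2) the standard deviation
#' (asymptotic standard error) of the fitted logEC50 is below one log unit;
#' (3) the extra-sum-of-squares test shows the odorant activated the
#' receptor significantly more than the vector-only control.
#'
#' @param fit An `or_fit` for the receptor data (from [fit_3pl()]).
#' @param or_data The receptor dataset used for the fit.
#' @param control_data The paired vector-control dataset (same columns).
#' @param alpha Significance level for criterion 3.
#' @return An `or_gate` list: `agonist` (logical), `reasons` (names of the
#'   failed criteria, empty if agonist), per-criterion flags, and the
#'   control-comparison `ExtraSS` result.
#' @export
agonist_gate <- function(fit, or_data, control_data, alpha = 0.05) {
  stopifnot(inherits(fit, "or_fit"))
  if (missing(control_data) || is.null(control_data)) {
    orevo_abort("a vector-control dataset is required", "orevo_control_error")
  }
  reasons <- character()
  ci_separated <- FALSE
  sd_ok <- FALSE
  if (!fit$converged) {
    reasons <- c(reasons, "fit_not_converged")
  } else {
    lo <- fit$ci_lower
    hi <- fit$ci_upper
    ci_separated <- !anyNA(c(lo[c("top", "bottom")], hi[c("top", "bottom")])) &&
      (lo["top"] > hi["bottom"] || lo["bottom"] > hi["top"])
    if (!ci_separated) reasons <- c(reasons, "top_bottom_ci_overlap")
    sd_ok <- !is.na(fit$se["logec50"]) && fit$se["logec50"] < 1
    if (!sd_ok) reasons <- c(reasons, "logec50_sd_too_large")
  }
  vs_control <- extra_ss_compare(or_data, control_data)
  above_control <- !is.na(vs_control$p) && vs_control$p < alpha
  if (!above_control) reasons <- c(reasons, "not_above_vector_control")
  structure(
    list(agonist = length(reasons) == 0L, reasons = reasons,
         ci_separated = ci_separated, sd_ok = sd_ok,
         above_control = above_control, vs_control = vs_control,
         alpha = alpha),
    class = "or_gate")
}

#' @export
print.or_gate <- function(x, ...) {
  cat("<or_gate> agonist:", x$agonist, "\n")
  if (length(x$reasons)) cat("failed:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Extra-sum-of-squares comparison of two dose-response datasets
#'
#' Asks whether one shared 3PL curve fits both datasets as well as two
#' separate curves. F = ((SS_pooled - SS_separate) / 3) /
#' (SS_separate / (n_total - 6)), with the p value from F(3, n_total - 6).
#'
#' @param data_a,data_b Tibbles with `log10_conc_M` and `response`.
#' @param n_starts Grid starts passed to the fit engine.
#' @return A one-row tibble: `F`, `df_num` (always 3), `df_den`, `p`,
#'   `ss_pooled`, `ss_separate`, `exact_fit` (TRUE when the separate fits
#'   are perfect but the pooled fit is not, reported as p = 0).
#' @export
extra_ss_compare <- function(data_a, data_b, n_starts = 5) {
  fa <- fit_3pl_engine(data_a$log10_conc_M, data_a$response, n_starts)
  fb <- fit_3pl_engine(data_b$log10_conc_M, data_b$response, n_starts)
  x <- c(data_a$log10_conc_M, data_b$log10_conc_M)
  y <- c(data_a$response, data_b$response)
  fp <- fit_3pl_engine(x, y, n_starts)
  ss_sep <- fa$ss + fb$ss
  ss_pool <- fp$ss
  n <- length(y)
  df_den <- n - 6L
  exact_fit <- FALSE
  if (ss_sep <= .Machine$double.eps * max(1, ss_pool)) {
    if (ss_pool > .Machine$double.eps) {
      exact_fit <- TRUE
      f <- Inf
      p <- 0
    } else {
      f <- 0
      p <- 1
    }
  } else {
    f <- max(0, ((ss_pool - ss_sep) / 3) / (ss_sep / df_den))
    p <- stats::pf(f, 3, df_den, lower.tail = FALSE)
  }
  tibble::tibble(F = f, df_num = 3L, df_den = df_den, p = p,
                 ss_pooled = ss_pool, ss_separate = ss_sep,
                 exact_fit = exact_fit)
}

#' Classify the functional relationship of a receptor pair
#'
#' Two receptors' dose-response curves to a common ligand are
#' `indistinguishable` when the extra-sum-of-squares test does not reject a
#' shared curve. When it rejects, the pair is `a_hyperfunctional` if
#' receptor A has both the lower EC50 (more potent) and the larger span
#' (more efficacious), `a_hypofunctional` in the mirror case, and
#' `undefined` when potency and efficacy change discordantly. If vector
#' controls are supplied, both receptors must pass [agonist_gate()], else
#' the pair is `not_comparable`.
#'
#' @param data_a,data_b Dose-response tibbles (`log10_conc_M`, `response`).
#' @param control_a,control_b Optional vector-control datasets; when given,
#'   the agonist gate is applied before classification.
#' @param alpha Significance level for the extra-SS test and gate.
#' @return An `or_class` one-row tibble: `label`, `F`, `df_num`, `df_den`,
#'   `p`, `d_logec50` (A minus B), `d_span` (A minus B).
#' @export
classify_pair <- function(data_a, data_b, control_a = NULL, control_b = NULL,
                          alpha = 0.05) {
  fit_a <- fit_3pl(data_a)
  fit_b <- fit_3pl(data_b)
  if (!is.null(control_a) || !is.null(control_b)) {
    if (is.null(control_a) || is.null(control_b)) {
      orevo_abort("supply controls for both receptors or neither",
                  "orevo_control_error")
    }
    gate_a <- agonist_gate(fit_a, data_a, control_a, alpha = alpha)
    gate_b <- agonist_gate(fit_b, data_b, control_b, alpha = alpha)
    if (!gate_a$agonist || !gate_b$agonist) {
      return(classification_row("not_comparable", NA, NA, NA, NA, NA, NA))
    }
  }
  cmp <- extra_ss_compare(data_a, data_b)
  d_logec50 <- unname(fit_a$coefficients["logec50"] -
                        fit_b$coefficients["logec50"])
  d_span <- fit_a$span - fit_b$span
  label <- if (is.na(cmp$p) || cmp$p >= alpha) {
    "indistinguishable"
  } else if (d_logec50 < 0 && d_span > 0) {
    "a_hyperfunctional"
  } else if (d_logec50 > 0 && d_span < 0) {
    "a_hypofunctional"
  } else {
    "undefined"
  }
  classification_row(label, cmp$F, cmp$df_num, cmp$df_den, cmp$p,
                     d_logec50, d_span)
}

classification_row <- function(label, f, df_num, df_den, p, d_logec50,
                               d_span) {
  res <- tibble::tibble(label = label, F = f, df_num = df_num,
                        df_den = df_den, p = p,
                        d_logec50 = d_logec50, d_span = d_span)
  structure(res, class = c("or_class", class(res)))
}

#' Display normalization for a set of dose-response curves
#'
#' Rescales the responses of an ortholog set for plotting. In
#' `"max_of_set"` mode the fitted bottom of the set's maximum-response
#' member is subtracted as baseline and responses are divided by that
#' member's baselined maximum, so the strongest curve peaks at 1. In
#' `"reference"` mode responses are divided by the reference receptor's
#' fitted maximum without baselining (preserving baseline differences).
#' Display-only: fits and tests always run on the unscaled responses.
#'
#' @param datasets Named list of dose-response tibbles (one per receptor).
#' @param mode `"max_of_set"` or `"reference"`.
#' @param reference Receptor name (required for `"reference"` mode).
#' @return Long tibble `receptor`, `log10_conc_M`, `response`,
#'   `scaled_response`.
#' @export
normalize_curve_set <- function(datasets, mode = c("max_of_set", "reference"),
                                reference = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(datasets) >= 1L, !is.null(names(datasets)))
  fits <- purrr::map(datasets, fit_3pl)
  tops <- purrr::map_dbl(fits, ~ unname(.x$coefficients["top"]))
  if (mode == "max_of_set") {
    lead <- names(which.max(tops))
    baseline <- unname(fits[[lead]]$coefficients["bottom"])
    denom <- tops[[lead]] - baseline
  } else {
    if (is.null(reference) || !reference %in% names(datasets)) {
      orevo_abort("reference mode requires a reference receptor present in the set",
                  "orevo_reference_error")
    }
    baseline <- 0
    denom <- tops[[reference]]
  }
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) {
    orevo_abort("zero span/maximum in the normalizing member",
                "orevo_degenerate_scope_error")
  }
  purrr::imap_dfr(datasets, function(d, nm) {
    tibble::tibble(receptor = nm,
                   log10_conc_M = d$log10_conc_M,
                   response = d$response,
                   scaled_response = (d$response - baseline) / denom)
  })
}
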