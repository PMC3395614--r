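#' Normalize a luciferase plate (or set of plates)
#'
#' Each well's firefly luminescence is first divided by its Renilla
#' luminescence (transfection-efficiency control), then rescaled by
#' \eqn{(L - L_{min}) / (L_{max} - L_{min})} where the minimum and maximum
#' ratios are taken over the declared scope: the whole measurement set
#' (`"plate_set"`, the default) or each `plate_id` separately (`"plate"`).
#' The scope and the anchors actually used are recorded in the result.
#'
#' @param measurements Tibble with columns `receptor`, `odor`, `replicate`,
#'   `firefly`, `renilla` and (for per-plate scope) `plate_id`. The odor
#'   column uses `"no_odor"` for the no-odor control wells.
#' @param scope `"plate_set"` or `"plate"`.
#' @return An `or_screen` object: list with `wells` (input plus `ratio` and
#'   `normalized` columns), `cells` (per receptor x odor replicate mean and
#'   standard error of the normalized response), and the normalization
#'   record (`scope`, `l_min`, `l_max`).
#' @export
normalize_plate <- function(measurements, scope = c("plate_set", "plate")) {
  scope <- match.arg(scope)
  m <- tibble::as_tibble(measurements)
  req <- c("receptor", "odor", "replicate", "firefly", "renilla")
  if (!all(req %in% names(m))) {
    orevo_abort(paste0("measurements must have columns: ",
                       paste(req, collapse = ", ")), "orevo_plate_error")
  }
  if (any(m$renilla <= 0)) {
    orevo_abort("Renilla luminescence must be positive in every well",
                "orevo_plate_error")
  }
  if (scope == "plate" && !"plate_id" %in% names(m)) {
    orevo_abort("per-plate scope requires a plate_id column",
                "orevo_plate_error")
  }
  m$ratio <- m$firefly / m$renilla
  if (scope == "plate_set") {
    l_min <- min(m$ratio)
    l_max <- max(m$ratio)
    if (l_max == l_min) {
      orevo_abort("degenerate normalization scope: L_max equals L_min",
                  "orevo_degenerate_scope_error")
    }
    m$normalized <- (m$ratio - l_min) / (l_max - l_min)
    anchors <- tibble::tibble(plate_id = NA_character_,
                              l_min = l_min, l_max = l_max)
  } else {
    m <- m |>
      dplyr::group_by(.data$plate_id) |>
      dplyr::mutate(l_min = min(.data$ratio), l_max = max(.data$ratio)) |>
      dplyr::ungroup()
    if (any(m$l_max == m$l_min)) {
      orevo_abort("degenerate normalization scope: L_max equals L_min",
                  "orevo_degenerate_scope_error")
    }
    m$normalized <- (m$ratio - m$l_min) / (m$l_max - m$l_min)
    anchors <- m |>
      dplyr::distinct(.data$plate_id, .data$l_min, .data$l_max)
    m$l_min <- NULL
    m$l_max <- NULL
  }
  cells <- m |>
    dplyr::group_by(.data$receptor, .data$odor) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_norm = mean(.data$normalized),
      se_norm = stats::sd(.data$normalized) / sqrt(dplyr::n()),
      .groups = "drop")
  structure(
    list(wells = m, cells = cells, scope = scope, anchors = anchors),
    class = "or_screen")
}

#' @export
print.or_screen <- function(x, ...) {
  cat("<or_screen> ", dplyr::n_distinct(x$wells$receptor), " receptor(s) x ",
      dplyr::n_distinct(x$wells$odor), " odor column(s), scope = ",
      x$scope, "\n", sep = "")
  print(x$cells, ...)
  invisible(x)
}

#' Call significant (agonist or inhibitory) screen responses
#'
#' Per receptor, each odor's normalized replicate values are compared with
#' the receptor's no-odor control wells by a two-sample t test (pooled
#' variance by default) at the Bonferroni-corrected level `alpha / n_odors`.
#' Significance is assessed two-sided, so inhibitory responses (odor mean
#' below the no-odor mean) are retained with their negative sign.
#'
#' @param screen An `or_screen` from [normalize_plate()].
#' @param n_odors Size of the screened panel used for the Bonferroni
#'   correction (default 42).
#' @param alpha Family-wise significance level before correction.
#' @param var_equal Pooled-variance t test (`TRUE`, default) or Welch.
#' @param control Odor label of the no-odor control wells.
#' @return An `or_calls` tibble: `receptor`, `odor`, `n`, `mean_response`
#'   (normalized odor mean minus normalized no-odor mean), `se`, `p_value`,
#'   `significant`.
#' @export
call_agonists <- function(screen, n_odors = 42, alpha = 0.05,
                          var_equal = TRUE, control = "no_odor") {
  stopifnot(inherits(screen, "or_screen"))
  wells <- screen$wells
  if (!control %in% wells$odor) {
    orevo_abort(sprintf("no-odor control wells ('%s') are missing", control),
                "orevo_control_error")
  }
  stats_tbl <- wells |>
    dplyr::group_by(.data$receptor, .data$odor) |>
    dplyr::summarise(n = dplyr::n(), m = mean(.data$normalized),
                     v = stats::var(.data$normalized), .groups = "drop")
  ctrl <- stats_tbl |>
    dplyr::filter(.data$odor == control) |>
    dplyr::select("receptor", n0 = "n", m0 = "m", v0 = "v")
  missing_ctrl <- setdiff(unique(stats_tbl$receptor), ctrl$receptor)
  if (length(missing_ctrl) > 0L) {
    orevo_abort(paste0("receptors without a no-odor control: ",
                       paste(missing_ctrl, collapse = ", ")),
                "orevo_control_error")
  }
  out <- stats_tbl |>
    dplyr::filter(.data$odor != control) |>
    dplyr::inner_join(ctrl, by = "receptor")
  if (any(out$n < 2L) || any(out$n0 < 2L)) {
    orevo_abort("at least two replicates per cell and control are required",
                "orevo_plate_error")
  }
  if (var_equal) {
    df <- out$n + out$n0 - 2
    sp2 <- ((out$n - 1) * out$v + (out$n0 - 1) * out$v0) / df
    se_diff <- sqrt(sp2 * (1 / out$n + 1 / out$n0))
  } else {
    se_a <- out$v / out$n
    se_b <- out$v0 / out$n0
    se_diff <- sqrt(se_a + se_b)
    df <- (se_a + se_b)^2 / (se_a^2 / (out$n - 1) + se_b^2 / (out$n0 - 1))
  }
  tstat <- (out$m - out$m0) / se_diff
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se_diff == 0 & out$m == out$m0] <- 1
  res <- tibble::tibble(
    receptor = out$receptor, odor = out$odor, n = out$n,
    mean_response = out$m - out$m0,
    se = sqrt(out$v / out$n),
    p_value = p,
    significant = p < alpha / n_odors)
  structure(res, class = c("or_calls", class(res)),
            alpha = alpha, n_odors = n_odors, var_equal = var_equal)
}

#' Tuning-display copy of screen responses
#'
#' Returns the response vector used for tuning curves and functional
#' distance: the signed mean response, with non-significant cells set to
#' zero (the display convention for the 42-odor panel).
#'
#' @param calls An `or_calls` tibble from [call_agonists()].
#' @param zero_nonsignificant Zero out non-significant cells (default TRUE).
#' @return Tibble `receptor`, `odor`, `response`, `significant`.
#' @export
tuning_responses <- function(calls, zero_nonsignificant = TRUE) {
  resp <- calls$mean_response
  if (zero_nonsignificant) resp[!calls$significant] <- 0
  tibble::tibble(receptor = calls$receptor, odor = calls$odor,
                 response = resp, significant = calls$significant)
}

#' Center-out tuning-curve ordering
#'
#' Orders the odor panel by the reference receptor's response (best ligand
#' at the center of the x-axis, subsequent ranks alternating right, left,
#' right, ...) and applies the same ordering to every variant receptor in
#' the set. Ties are broken by odor label.
#'
#' @param responses Tibble `receptor`, `odor`, `response` (typically from
#'   [tuning_responses()]).
#' @param reference Receptor label whose responses define the ordering.
#' @return An `or_tuning` tibble: `receptor`, `odor`, `rank`, `position`
#'   (1-based x-axis slot), `response`; every receptor shares the ordering.
#' @export
order_tuning_curve <- function(responses, reference) {
  if (!reference %in% responses$receptor) {
    orevo_abort(sprintf("reference receptor '%s' not present", reference),
                "orevo_reference_error")
  }
  ref <- responses |>
    dplyr::filter(.data$receptor == reference) |>
    dplyr::arrange(dplyr::desc(.data$response), .data$odor) |>
    dplyr::mutate(rank = dplyr::row_number())
  n <- nrow(ref)
  center <- ceiling(n / 2)
  offset <- ifelse(ref$rank %% 2 == 0, ref$rank %/% 2, -(ref$rank - 1) %/% 2)
  ref$position <- center + offset
  key <- ref |> dplyr::select("odor", "rank", "position")
  out <- responses |>
    dplyr::inner_join(key, by = "odor") |>
    dplyr::arrange(.data$receptor, .data$position)
  structure(out, class = c("or_tuning", class(out)), reference = reference)
}

#' Plot a center-out tuning curve set
#'
#' @param object An `or_tuning` from [order_tuning_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot or_tuning
#' @export
autoplot.or_tuning <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$response,
                                       colour = .data$receptor)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "odor (center-out by reference response)",
                  y = "normalized response") +
    ggplot2::theme_minimal()
}
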