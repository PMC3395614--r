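#' Functional distance between two receptors' odor-panel profiles
#'
#' The functional distance is one minus the Pearson correlation of the two
#' receptors' response vectors over the shared odor panel (conventionally
#' the significance-zeroed display copies). A pair is excluded when either
#' member responds to fewer odors than `min_responsive`.
#'
#' @param resp_a,resp_b Numeric response vectors in the same odor order.
#' @param min_responsive Minimum responsive (non-zero) odor count per
#'   member for the pair to be included (default 3; the exact threshold
#'   convention is configurable).
#' @param n_responsive_a,n_responsive_b Optional explicit responsive-odor
#'   counts; by default the non-zero entries are counted.
#' @return A one-row tibble: `r` (Pearson R, `NA` when undefined), `distance`
#'   (`1 - r`), `n_responsive_a`, `n_responsive_b`, `included`, `defined`.
#'   Excluded pairs carry `NA` distance.
#' @export
functional_distance <- function(resp_a, resp_b, min_responsive = 3,
                                n_responsive_a = NULL,
                                n_responsive_b = NULL) {
  if (length(resp_a) != length(resp_b)) {
    orevo_abort("response vectors must have equal length and odor order",
                "orevo_profile_error")
  }
  na <- n_responsive_a %||% sum(resp_a != 0)
  nb <- n_responsive_b %||% sum(resp_b != 0)
  included <- na >= min_responsive && nb >= min_responsive
  defined <- stats::sd(resp_a) > 0 && stats::sd(resp_b) > 0
  r <- if (included && defined) stats::cor(resp_a, resp_b) else NA_real_
  tibble::tibble(r = r, distance = 1 - r,
                 n_responsive_a = na, n_responsive_b = nb,
                 included = included, defined = defined)
}

#' Spearman rank correlation
#'
#' Rank correlation with mid-ranks for ties and a two-sided p value (t
#' approximation, the standard treatment in the presence of ties).
#'
#' @param x,y Paired numeric vectors (at least 4 complete pairs).
#' @return One-row tibble `rho`, `p`, `n`, `defined` (`FALSE` when either
#'   variable is constant).
#' @export
rank_correlation <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 4L) {
    orevo_abort("at least 4 complete pairs are required", "orevo_stat_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = length(x),
                          defined = FALSE))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
                 defined = TRUE)
}

#' Common-ligand response rate within a stratum
#'
#' Fraction of comparison receptors in a group table that respond to the
#' group's common ligand, with exact counts.
#'
#' @param table Tibble with a logical `responder` column and optional
#'   `relationship` (e.g. `"ortholog"`, `"paralog"`) and `species_pair`
#'   columns.
#' @param relationship,species_pair Optional stratum filters.
#' @return One-row tibble `responders`, `n`, `fraction`, `percent`
#'   (rounded to whole percent for display; exact counts carried).
#' @export
common_ligand_rate <- function(table, relationship = NULL,
                               species_pair = NULL) {
  t <- tibble::as_tibble(table)
  if (!is.null(relationship)) {
    t <- dplyr::filter(t, .data$relationship %in% !!relationship)
  }
  if (!is.null(species_pair)) {
    t <- dplyr::filter(t, .data$species_pair %in% !!species_pair)
  }
  if (nrow(t) == 0L) {
    orevo_abort("empty stratum: no rows match the filter", "orevo_stat_error")
  }
  responders <- sum(t$responder)
  n <- nrow(t)
  tibble::tibble(responders = responders, n = n,
                 fraction = responders / n,
                 percent = round(100 * responders / n))
}

#' Wilcoxon rank-sum comparison with a z statistic
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test using the normal
#' approximation with the tie-corrected variance. The sign convention is
#' `z < 0` when `group_a` is stochastically smaller than `group_b`.
#'
#' @param group_a,group_b Numeric vectors (at least 3 values each).
#' @return One-row tibble `z`, `p`, `w` (rank-sum statistic of group A
#'   minus its minimum), `n_a`, `n_b`, `defined` (`FALSE` when all values
#'   are tied across both groups).
#' @export
ranksum_compare <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  n_a <- length(group_a)
  n_b <- length(group_b)
  if (n_a < 3L || n_b < 3L) {
    orevo_abort("each group needs at least 3 values", "orevo_stat_error")
  }
  pooled <- c(group_a, group_b)
  if (length(unique(pooled)) == 1L) {
    return(tibble::tibble(z = NA_real_, p = NA_real_, w = NA_real_,
                          n_a = n_a, n_b = n_b, defined = FALSE))
  }
  rk <- rank(pooled)
  w <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  n <- n_a + n_b
  mu <- n_a * n_b / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
  z <- (w - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(z = z, p = p, w = w, n_a = n_a, n_b = n_b, defined = TRUE)
}

#' Distribution summary (box-plot order statistics)
#'
#' Minimum, 10/25/50/75/90% quantiles (linear interpolation) and maximum.
#'
#' @param values Numeric vector (at least one value).
#' @return One-row tibble `n`, `min`, `q10`, `q25`, `median`, `q75`, `q90`,
#'   `max`.
#' @export
summarize_distribution <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    orevo_abort("at least one value is required", "orevo_stat_error")
  }
  q <- stats::quantile(values, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE,
                       type = 7)
  tibble::tibble(n = length(values), min = min(values),
                 q10 = q[1], q25 = q[2], median = q[3], q75 = q[4],
                 q90 = q[5], max = max(values))
}

#' Join sequence metrics with functional distances
#'
#' Builds the per-pair table relating sequence divergence to functional
#' divergence: one row per ortholog pair with Jukes-Cantor distance,
#' Grantham distances, omega and functional distance.
#'
#' @param seq_tbl Output of [pairwise_metrics()].
#' @param func_tbl Tibble `id_a`, `id_b`, `distance` (functional distance,
#'   e.g. accumulated from [functional_distance()] per pair).
#' @return Joined tibble; pairs missing from either side carry `NA`.
#' @export
seq_func_table <- function(seq_tbl, func_tbl) {
  dplyr::full_join(
    seq_tbl,
    dplyr::select(func_tbl, "id_a", "id_b",
                  functional_distance = "distance"),
    by = c("id_a", "id_b"))
}
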