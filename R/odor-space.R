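# Odor-panel selection in physicochemical descriptor space.

# seeded greedy k-means++ initialization: first center uniform at random;
# each subsequent center is sampled proportional to squared distance to
# the nearest chosen center, drawing several candidates per step and
# keeping the one that most reduces the total potential
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  n_cand <- 2L + as.integer(floor(log(max(k, 2))))
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1L)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    cand <- sample.int(n, n_cand, prob = probs, replace = TRUE)
    pot <- vapply(cand, function(ci) {
      sum(pmin(d2, rowSums((x - matrix(x[ci, ], n, ncol(x),
                                       byrow = TRUE))^2)))
    }, numeric(1))
    pick <- cand[which.min(pot)]
    centers[i + 1L] <- pick
    d2 <- pmin(d2, rowSums((x - matrix(x[pick, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  x[centers, , drop = FALSE]
}

#' Select a chemically diverse odor panel by k-means
#'
#' Standardizes the descriptor columns (z-score), partitions the odorants
#' into `k` clusters by seeded k-means (k-means++-style initialization,
#' Euclidean metric), and selects one odorant per cluster: the known-active
#' member closest to the cluster centroid, or, if the cluster contains no
#' known active, the member closest to the centroid. Deterministic for a
#' fixed seed.
#'
#' @param descriptors Tibble with an `id` column, a logical `active`
#'   column (previously shown to activate at least one receptor), and
#'   numeric descriptor columns (everything else).
#' @param k Panel size (default 42).
#' @param seed Integer seed controlling initialization.
#' @param n_init Number of seeded restarts; the partition with the lowest
#'   total within-cluster sum of squares is kept.
#' @return An `or_panel` tibble: `cluster`, `id`, `dist_to_centroid`,
#'   `rule_used` (`"known_active"` or `"nearest"`), one row per cluster.
#'   The full cluster assignment is attached as attribute `assignment`.
#' @export
select_panel <- function(descriptors, k = 42, seed = 1L, n_init = 10) {
  d <- tibble::as_tibble(descriptors)
  if (!all(c("id", "active") %in% names(d))) {
    orevo_abort("descriptors must have 'id' and 'active' columns",
                "orevo_panel_error")
  }
  num_cols <- setdiff(names(d), c("id", "active"))
  x <- as.matrix(d[num_cols])
  if (ncol(x) < 2L) {
    orevo_abort("at least 2 descriptor columns are required",
                "orevo_panel_error")
  }
  if (anyNA(x)) {
    orevo_abort("descriptor matrix must not contain missing values",
                "orevo_panel_error")
  }
  if (k > nrow(x)) {
    orevo_abort("k must not exceed the number of odorants",
                "orevo_panel_error")
  }
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  x <- scale(x, center = TRUE, scale = sds)
  if (k == nrow(x)) {
    # every odorant is its own (singleton) cluster
    asg <- tibble::tibble(id = d$id, active = d$active,
                          cluster = seq_len(k), dist_to_centroid = 0)
    pick <- tibble::tibble(cluster = seq_len(k), id = d$id,
                           dist_to_centroid = 0,
                           rule_used = ifelse(d$active, "known_active",
                                              "nearest"))
    return(structure(pick, class = c("or_panel", class(pick)),
                     assignment = asg, seed = seed, k = k))
  }
  km <- withr::with_seed(seed, {
    best <- NULL
    for (attempt in seq_len(n_init)) {
      init <- kmeanspp_init(x, k)
      fit <- tryCatch(
        stats::kmeans(x, centers = init, iter.max = 100),
        error = function(e) NULL)
      # an empty cluster after convergence is handled by re-seeding
      if (is.null(fit) || any(fit$size == 0)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) {
      orevo_abort("k-means failed to produce k non-empty clusters",
                  "orevo_panel_error")
    }
    best
  })
  dist_to_centroid <- sqrt(rowSums((x - km$centers[km$cluster, ,
                                                   drop = FALSE])^2))
  asg <- tibble::tibble(id = d$id, active = d$active,
                        cluster = km$cluster,
                        dist_to_centroid = dist_to_centroid)
  pick <- asg |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_modify(function(g, key) {
      cand <- if (any(g$active)) g[g$active, ] else g
      rule <- if (any(g$active)) "known_active" else "nearest"
      best <- cand[order(cand$dist_to_centroid, cand$id), ][1, ]
      tibble::tibble(id = best$id, dist_to_centroid = best$dist_to_centroid,
                     rule_used = rule)
    }) |>
    dplyr::ungroup()
  structure(pick, class = c("or_panel", class(pick)),
            assignment = asg, seed = seed, k = k)
}

#' Plot a selected odor panel in principal-component space
#'
#' Projects the standardized descriptor matrix onto its first two principal
#' components and highlights the selected panel.
#'
#' @param descriptors The descriptor tibble passed to [select_panel()].
#' @param panel The resulting `or_panel`.
#' @return A ggplot.
#' @export
plot_panel <- function(descriptors, panel) {
  num_cols <- setdiff(names(descriptors), c("id", "active"))
  x <- scale(as.matrix(descriptors[num_cols]))
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  proj <- tibble::tibble(id = descriptors$id,
                         pc1 = pc$x[, 1], pc2 = pc$x[, 2],
                         selected = descriptors$id %in% panel$id)
  ggplot2::ggplot(proj, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected,
                                     size = .data$selected), alpha = 0.7) +
    ggplot2::scale_size_manual(values = c(`FALSE` = 0.7, `TRUE` = 2)) +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}
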