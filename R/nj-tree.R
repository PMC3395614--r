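#' Neighbor-Joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}) on a symmetric, nonnegative,
#' zero-diagonal distance matrix. With two taxa the result is the single
#' edge connecting them (total path length equal to their distance).
#'
#' @param dm Symmetric numeric matrix with zero diagonal and row/column
#'   labels, or a `dist` object.
#' @return An unrooted `phylo` tree with branch lengths; write with
#'   [write_newick()].
#' @export
neighbor_joining_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    orevo_abort("dm must be a square distance matrix", "orevo_distance_error")
  }
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
  }
  if (any(dm < 0)) {
    orevo_abort("distances must be nonnegative", "orevo_distance_error")
  }
  if (max(abs(dm - t(dm))) > 1e-8) {
    orevo_abort("distance matrix must be symmetric", "orevo_distance_error")
  }
  if (any(diag(dm) != 0)) {
    orevo_abort("distance matrix must have a zero diagonal",
                "orevo_distance_error")
  }
  n <- nrow(dm)
  if (n < 2L) {
    orevo_abort("at least two taxa are required", "orevo_distance_error")
  }
  if (n == 2L) {
    txt <- sprintf("(%s:%.10g,%s:%.10g);",
                   rownames(dm)[1], dm[1, 2] / 2,
                   rownames(dm)[2], dm[1, 2] / 2)
    return(ape::read.tree(text = txt))
  }
  ape::nj(stats::as.dist(dm))
}

#' Write a tree in Newick format
#'
#' @param tree A `phylo` object.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Distance matrix from a pairwise-metric table
#'
#' Assembles the symmetric matrix needed for tree building from the long
#' pair table produced by [pairwise_metrics()] (or any tibble with `id_a`,
#' `id_b` and a numeric metric column).
#'
#' @param pairs_tbl Tibble with columns `id_a`, `id_b` and the metric.
#' @param metric Name of the metric column (e.g. `"grantham_orf"`).
#' @return A symmetric matrix over all labels appearing in the table;
#'   missing pairs are `NA`.
#' @export
metric_dist_matrix <- function(pairs_tbl, metric) {
  labs <- sort(unique(c(pairs_tbl$id_a, pairs_tbl$id_b)))
  m <- matrix(NA_real_, length(labs), length(labs),
              dimnames = list(labs, labs))
  diag(m) <- 0
  m[cbind(pairs_tbl$id_a, pairs_tbl$id_b)] <- pairs_tbl[[metric]]
  m[cbind(pairs_tbl$id_b, pairs_tbl$id_a)] <- pairs_tbl[[metric]]
  m
}
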