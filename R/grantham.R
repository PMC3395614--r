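#' Grantham amino-acid properties
#'
#' Residue-level physicochemical properties underlying Grantham's distance:
#' composition `c` (atomic weight ratio of hetero elements in side chains),
#' polarity `p`, and molecular volume `v`.
#'
#' @return A tibble with columns `aa` (one-letter code), `c`, `p`, `v`.
#' @export
grantham_properties <- function() {
  tibble::tribble(
    ~aa,   ~c,   ~p,   ~v,
    "S", 1.42,  9.2,  32,
    "R", 0.65, 10.5, 124,
    "L", 0.00,  4.9, 111,
    "P", 0.39,  8.0,  32.5,
    "T", 0.71,  8.6,  61,
    "A", 0.00,  8.1,  31,
    "V", 0.00,  5.9,  84,
    "G", 0.74,  9.0,   3,
    "I", 0.00,  5.2, 111,
    "F", 0.00,  5.2, 132,
    "Y", 0.20,  6.2, 136,
    "C", 2.75,  5.5,  55,
    "H", 0.58, 10.4,  96,
    "Q", 0.89, 10.5,  85,
    "N", 1.33, 11.6,  56,
    "K", 0.33, 11.3, 119,
    "D", 1.38, 13.0,  54,
    "E", 0.92, 12.3,  83,
    "M", 0.00,  5.7, 105,
    "W", 0.13,  5.4, 170
  )
}

#' Grantham distance matrix
#'
#' Builds the 20 x 20 amino-acid distance matrix from composition, polarity
#' and molecular volume:
#' \deqn{D_{ij} = \rho \sqrt{\alpha (c_i - c_j)^2 + \beta (p_i - p_j)^2 +
#'   \gamma (v_i - v_j)^2}}
#' The scale factor `rho` is chosen so that the mean distance over the 190
#' unordered heterotypic residue pairs is exactly 100, which reproduces the
#' published matrix (e.g. Ser-Leu = 145) to rounding.
#'
#' @param alpha,beta,gamma Property weights (defaults are Grantham's).
#' @param properties Residue property table, see [grantham_properties()].
#' @return A symmetric 20 x 20 numeric matrix with zero diagonal, rows and
#'   columns named by one-letter amino-acid code.
#' @export
grantham_matrix <- function(alpha = 1.833, beta = 0.1018, gamma = 0.000399,
                            properties = grantham_properties()) {
  stopifnot(nrow(properties) == 20L)
  d2 <- alpha * outer(properties$c, properties$c, "-")^2 +
    beta  * outer(properties$p, properties$p, "-")^2 +
    gamma * outer(properties$v, properties$v, "-")^2
  d <- sqrt(d2)
  rho <- 100 / mean(d[upper.tri(d)])
  d <- rho * d
  dimnames(d) <- list(properties$aa, properties$aa)
  d
}

#' Mean Grantham distance between two aligned protein sequences
#'
#' Averages the per-site Grantham matrix entry over the compared alignment
#' positions. With `positions = NULL` every position where both sequences
#' carry a residue (no gap) is compared; passing a position set restricts the
#' comparison, e.g. to binding-site residues. Sites where either sequence is
#' gapped are dropped (pairwise deletion).
#'
#' @param pair A [coding_pair()] object, or anything with `aa_a`/`aa_b`
#'   fields holding aligned amino-acid strings.
#' @param positions Optional integer vector of 1-based alignment positions
#'   (see [residue_positions()]); `NULL` compares the full alignment.
#' @param table Distance matrix from [grantham_matrix()].
#' @return Mean distance (0 iff the sequences are identical at all compared
#'   positions).
#' @export
grantham_distance <- function(pair, positions = NULL,
                              table = grantham_matrix()) {
  a <- strsplit(pair$aa_a, "")[[1]]
  b <- strsplit(pair$aa_b, "")[[1]]
  stopifnot(length(a) == length(b))
  if (is.null(positions)) {
    positions <- seq_along(a)
  } else {
    positions <- as.integer(positions)
    if (anyDuplicated(positions) || any(positions < 1L) ||
        any(positions > length(a))) {
      orevo_abort("positions must be unique and within alignment bounds",
                  "orevo_position_error")
    }
  }
  a <- a[positions]
  b <- b[positions]
  keep <- a != "-" & b != "-" & a != "X" & b != "X"
  if (!any(keep)) {
    orevo_abort("no comparable (ungapped) positions between the sequences",
                "orevo_no_sites_error")
  }
  mean(table[cbind(a[keep], b[keep])])
}

#' Define a named set of alignment positions
#'
#' Light wrapper used to carry e.g. the 22 predicted ligand-binding residues
#' as 1-based coordinates into a reference amino-acid alignment.
#'
#' @param positions Integer vector of unique 1-based positions.
#' @param label Name of the set (e.g. `"22AA"`).
#' @return An integer vector with a `label` attribute.
#' @export
residue_positions <- function(positions, label = "positions") {
  positions <- as.integer(positions)
  if (anyDuplicated(positions)) {
    orevo_abort("positions must be unique", "orevo_position_error")
  }
  structure(positions, label = label)
}
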