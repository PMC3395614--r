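#' Pairwise sequence metrics for a set of aligned coding sequences
#'
#' For every requested pair, computes the Jukes-Cantor nucleotide distance,
#' the mean Grantham distance over the full open reading frame and
#' (optionally) over a binding-site position subset, and the Nei-Gojobori
#' dN, dS and omega. Saturated distances are reported as `NA`.
#'
#' @param alignment Named character vector of codon-aligned nucleotide
#'   sequences (e.g. from [read_alignment_fasta()]).
#' @param pairs Data frame with columns `id_a`, `id_b` naming alignment
#'   members; defaults to all unordered pairs.
#' @param positions Optional [residue_positions()] set (1-based amino-acid
#'   alignment coordinates) for the binding-site Grantham column.
#' @param table Grantham matrix, see [grantham_matrix()].
#' @return A tibble with one row per pair: `id_a`, `id_b`, `jc`,
#'   `grantham_orf`, `grantham_22aa` (`NA` when no position set is given),
#'   `dn`, `ds`, `omega`.
#' @export
pairwise_metrics <- function(alignment, pairs = NULL, positions = NULL,
                             table = grantham_matrix()) {
  if (is.null(names(alignment)) || anyDuplicated(names(alignment))) {
    orevo_abort("alignment sequences must carry unique names",
                "orevo_alignment_error")
  }
  if (is.null(pairs)) {
    ids <- names(alignment)
    pairs <- tidyr::expand_grid(id_a = ids, id_b = ids) |>
      dplyr::filter(match(.data$id_a, ids) < match(.data$id_b, ids))
  }
  missing <- setdiff(unique(c(pairs$id_a, pairs$id_b)), names(alignment))
  if (length(missing) > 0L) {
    orevo_abort(paste0("pair member(s) absent from alignment: ",
                       paste(missing, collapse = ", ")),
                "orevo_alignment_error")
  }
  one <- function(id_a, id_b) {
    pr <- coding_pair(alignment[[id_a]], alignment[[id_b]],
                      id_a = id_a, id_b = id_b)
    jc <- tryCatch(jukes_cantor_distance(pr),
                   orevo_saturation_error = function(e) NA_real_)
    g_orf <- grantham_distance(pr, table = table)
    g_sub <- if (is.null(positions)) NA_real_ else {
      grantham_distance(pr, positions = positions, table = table)
    }
    ng <- nei_gojobori_omega(pr)
    tibble::tibble(id_a = id_a, id_b = id_b, jc = jc,
                   grantham_orf = g_orf, grantham_22aa = g_sub,
                   dn = ng$dN, ds = ng$dS, omega = ng$omega)
  }
  purrr::map2_dfr(pairs$id_a, pairs$id_b, one)
}
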