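# Nei-Gojobori (1986) pairwise synonymous/nonsynonymous analysis.
#
# Site counting: at each codon position the three possible single-nucleotide
# changes are classified; the synonymous-site count of a codon is the summed
# fraction of synonymous changes (changes to stop codons count as
# nonsynonymous so that S + N = 3 per codon). Difference counting: codons
# differing at k positions are resolved by averaging the per-step
# synonymous/nonsynonymous classification over all k! single-step pathways
# that avoid stop codons; if every pathway crosses a stop, the average over
# all pathways is used.

.ng_cache <- new.env(parent = emptyenv())

ng_syn_site_table <- function() {
  if (!is.null(.ng_cache$sites)) return(.ng_cache$sites)
  code <- genetic_code()
  nts <- c("A", "C", "G", "T")
  codons <- names(code)[code != "*"]
  s <- vapply(codons, function(codon) {
    cv <- strsplit(codon, "")[[1]]
    aa <- code[[codon]]
    syn <- 0
    for (pos in 1:3) {
      for (nt in setdiff(nts, cv[pos])) {
        alt <- cv
        alt[pos] <- nt
        alt_aa <- code[[paste(alt, collapse = "")]]
        if (alt_aa != "*" && alt_aa == aa) syn <- syn + 1 / 3
      }
    }
    syn
  }, numeric(1))
  .ng_cache$sites <- s
  s
}

# all orderings of a small index vector (k <= 3 in practice)
all_orderings <- function(idx) {
  k <- length(idx)
  if (k <= 1L) return(list(idx))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in all_orderings(idx[-i])) out[[length(out) + 1L]] <- c(idx[i], rest)
  }
  out
}

# average (synonymous, nonsynonymous) difference counts between two sense
# codons over single-step mutational pathways
ng_codon_diffs <- function(codon_a, codon_b) {
  key <- paste0(codon_a, codon_b)
  cached <- .ng_cache[[key]]
  if (!is.null(cached)) return(cached)
  code <- genetic_code()
  va <- strsplit(codon_a, "")[[1]]
  vb <- strsplit(codon_b, "")[[1]]
  pos <- which(va != vb)
  if (length(pos) == 0L) {
    res <- c(sd = 0, nd = 0)
    .ng_cache[[key]] <- res
    return(res)
  }
  paths <- all_orderings(pos)
  tally <- function(order) {
    cur <- va
    sd <- nd <- 0
    crosses_stop <- FALSE
    for (p in order) {
      aa_before <- code[[paste(cur, collapse = "")]]
      cur[p] <- vb[p]
      nxt <- paste(cur, collapse = "")
      aa_after <- code[[nxt]]
      if (aa_after == "*" && nxt != codon_b) crosses_stop <- TRUE
      if (aa_before == aa_after && aa_before != "*") sd <- sd + 1 else nd <- nd + 1
    }
    c(sd, nd, crosses_stop)
  }
  counts <- vapply(paths, tally, numeric(3))
  ok <- counts[3, ] == 0
  use <- if (any(ok)) counts[, ok, drop = FALSE] else counts
  res <- c(sd = mean(use[1, ]), nd = mean(use[2, ]))
  .ng_cache[[key]] <- res
  res
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) method
#'
#' Counts synonymous and nonsynonymous sites and differences over the
#' codon-aligned pair (codons gapped in either member are dropped), converts
#' the proportions to rates with the Jukes-Cantor correction, and reports
#' \eqn{\omega = dN/dS}. Multiple-hit codons are resolved by uniform
#' averaging over all single-step pathways that avoid stop codons.
#'
#' @param pair A [coding_pair()].
#' @return A one-row tibble with columns `S`, `N` (site counts averaged over
#'   the two sequences), `Sd`, `Nd` (difference counts), `pS`, `pN`, `dS`,
#'   `dN`, `omega`, and flags `omega_defined`, `saturated_s`, `saturated_n`.
#'   `omega` is `NA` with `omega_defined = FALSE` when `dS` is zero or
#'   saturated.
#' @export
nei_gojobori_omega <- function(pair) {
  cc <- comparable_codons(pair)
  n_codons <- length(cc$a)
  if (n_codons == 0L) {
    orevo_abort("no comparable (ungapped) codons", "orevo_no_sites_error")
  }
  site_tab <- ng_syn_site_table()
  s_a <- sum(site_tab[cc$a])
  s_b <- sum(site_tab[cc$b])
  S <- (s_a + s_b) / 2
  N <- 3 * n_codons - S

  diffs <- mapply(ng_codon_diffs, cc$a, cc$b)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])

  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0

  saturated_s <- pS >= 0.75
  saturated_n <- pN >= 0.75
  dS <- if (saturated_s) NA_real_ else jc_correct(pS)
  dN <- if (saturated_n) NA_real_ else jc_correct(pN)

  omega_defined <- !is.na(dS) && dS > 0 && !is.na(dN)
  omega <- if (omega_defined) dN / dS else NA_real_

  tibble::tibble(
    id_a = pair$id_a, id_b = pair$id_b,
    n_codons = n_codons,
    S = S, N = N, Sd = Sd, Nd = Nd,
    pS = pS, pN = pN, dS = dS, dN = dN,
    omega = omega, omega_defined = omega_defined,
    saturated_s = saturated_s, saturated_n = saturated_n)
}
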