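#' Jukes-Cantor nucleotide distance
#'
#' One-parameter correction of the observed mismatch proportion,
#' \eqn{d = -\frac{3}{4}\log(1 - \frac{4}{3} p)}, over sites where both
#' sequences are ungapped (codons gapped in either member are dropped).
#'
#' @param pair A [coding_pair()].
#' @return Distance in substitutions per site.
#' @section Errors: a mismatch proportion \eqn{p \ge 3/4} is outside the
#'   model's domain and raises a saturation error.
#' @export
jukes_cantor_distance <- function(pair) {
  cc <- comparable_codons(pair)
  if (length(cc$a) == 0L) {
    orevo_abort("no comparable (ungapped) codons", "orevo_no_sites_error")
  }
  a <- strsplit(paste(cc$a, collapse = ""), "")[[1]]
  b <- strsplit(paste(cc$b, collapse = ""), "")[[1]]
  p <- mean(a != b)
  jc_correct(p, what = "nucleotide distance")
}

# closed-form JC correction shared with the NG86 rate step
jc_correct <- function(p, what = "proportion") {
  if (p >= 0.75) {
    orevo_abort(
      sprintf("%s saturated: observed proportion %.3f >= 3/4, Jukes-Cantor distance undefined",
              what, p),
      "orevo_saturation_error")
  }
  -0.75 * log(1 - 4 * p / 3)
}
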