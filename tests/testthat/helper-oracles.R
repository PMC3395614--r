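# Independent oracles used to freeze expected values. These deliberately
# re-derive quantities by brute force / closed form rather than calling the
# package's own code paths.

oracle_code <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

# brute-force NG86 synonymous-site count for one codon: classify each of
# the nine possible single-nucleotide changes; changes to stop codons are
# nonsynonymous (S + N = 3 per codon)
oracle_syn_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  cv <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    for (nt in nts[nts != cv[pos]]) {
      alt <- cv
      alt[pos] <- nt
      alt_codon <- paste(alt, collapse = "")
      if (oracle_code[[alt_codon]] == oracle_code[[codon]] &&
          oracle_code[[alt_codon]] != "*") {
        syn <- syn + 1 / 3
      }
    }
  }
  syn
}

# exhaustive pathway enumeration of (Sd, Nd) between two sense codons:
# every ordering of the differing positions is walked step by step;
# orderings passing through a stop codon are excluded unless all do
oracle_codon_diffs <- function(codon_a, codon_b) {
  va <- strsplit(codon_a, "")[[1]]
  vb <- strsplit(codon_b, "")[[1]]
  pos <- which(va != vb)
  if (length(pos) == 0) return(c(0, 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(r) c(v[i], r))
    }), recursive = FALSE)
  }
  rows <- lapply(perms(pos), function(order) {
    cur <- va
    sd <- nd <- 0
    stop_hit <- FALSE
    for (p in order) {
      before <- oracle_code[[paste(cur, collapse = "")]]
      cur[p] <- vb[p]
      after <- oracle_code[[paste(cur, collapse = "")]]
      if (after == "*") stop_hit <- TRUE
      if (before == after && before != "*") sd <- sd + 1 else nd <- nd + 1
    }
    c(sd, nd, stop_hit)
  })
  m <- do.call(rbind, rows)
  keep <- if (any(m[, 3] == 0)) m[m[, 3] == 0, , drop = FALSE] else m
  c(mean(keep[, 1]), mean(keep[, 2]))
}

oracle_jc <- function(p) -0.75 * log(1 - 4 * p / 3)

# exact Wilcoxon rank-sum distribution by enumeration of group assignments
oracle_ranksum_w <- function(a, b) {
  sum(rank(c(a, b))[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

sense_codon_list <- names(oracle_code)[oracle_code != "*"]

# quick dose-response dataset from true 3PL parameters
make_dr <- function(bottom, top, logec50, x = seq(-8, -2, by = 1),
                    n_reps = 3, sd = 0, seed = NULL) {
  f <- function() {
    xx <- rep(x, each = n_reps)
    mu <- bottom + (top - bottom) / (1 + 10^(logec50 - xx))
    tibble::tibble(log10_conc_M = xx,
                   response = mu + stats::rnorm(length(xx), 0, sd))
  }
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}

# minimal null plate: one receptor, n_odors odors plus no-odor control,
# all wells drawn from the same distribution
make_null_plate <- function(n_odors = 42, n_reps = 3, sd = 0.05) {
  odors <- c(sprintf("o%02d", seq_len(n_odors)), "no_odor")
  tibble::tibble(
    receptor = "R",
    odor = rep(odors, each = n_reps),
    replicate = rep(seq_len(n_reps), times = length(odors)),
    firefly = 100 * (1 + stats::rnorm(length(odors) * n_reps, 0, sd)),
    renilla = 100,
    plate_id = "p1")
}
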