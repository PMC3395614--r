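# Seeded simulators generating every input format with known ground truth.
#
# Sequence evolution uses an acceptance-probability scheme: point mutations
# are proposed uniformly over nucleotide sites (transition/transversion
# weighted), accepted with probability 1 if synonymous and with probability
# equal to the target omega if nonsynonymous; proposals creating stop
# codons are always rejected. Because proposals are uniform (the mutation
# model underlying the Nei-Gojobori site counting), the realized dN/dS of
# the output tracks the target omega.

sense_codons <- function() {
  code <- genetic_code()
  names(code)[code != "*"]
}

random_orf <- function(n_codons) {
  cods <- c("ATG", sample(sense_codons(), n_codons - 1L, replace = TRUE))
  paste(cods, collapse = "")
}

# evolve one branch; returns list(nt, n_syn, n_nonsyn accepted)
evolve_branch <- function(nt, n_proposals, omega, ts_tv = 1) {
  code <- genetic_code()
  v <- strsplit(nt, "")[[1]]
  p_syn <- if (omega <= 1) 1 else 1 / omega
  p_nonsyn <- min(omega, 1)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  nts <- c("A", "C", "G", "T")
  n_syn <- n_nonsyn <- 0L
  if (n_proposals > 0L) {
    sites <- sample.int(length(v), n_proposals, replace = TRUE)
    for (site in sites) {
      cur <- v[site]
      tv <- setdiff(nts, c(cur, transition[[cur]]))
      alts <- c(transition[[cur]], tv)
      alt <- sample(alts, 1L, prob = c(ts_tv, 1, 1))
      cod_i <- (site - 1L) %/% 3L
      old_codon <- paste(v[cod_i * 3L + 1:3], collapse = "")
      new_v <- v[cod_i * 3L + 1:3]
      new_v[(site - 1L) %% 3L + 1L] <- alt
      new_codon <- paste(new_v, collapse = "")
      if (code[[new_codon]] == "*") next
      syn <- code[[new_codon]] == code[[old_codon]]
      p_accept <- if (syn) p_syn else p_nonsyn
      if (runif(1) <= p_accept) {
        v[site] <- alt
        if (syn) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
      }
    }
  }
  list(nt = paste(v, collapse = ""), n_syn = n_syn, n_nonsyn = n_nonsyn)
}

#' Simulate a diverged ortholog coding-sequence pair
#'
#' Draws a random stop-free ancestral open reading frame and evolves two
#' descendants independently. Substitutions per branch are Poisson with
#' mean `subs_per_site * 3 * n_codons` proposals; synonymous proposals are
#' accepted with probability 1 and nonsynonymous proposals with probability
#' `omega` (for `omega > 1` the scheme is inverted: nonsynonymous changes
#' are always accepted and synonymous changes accepted with probability
#' `1/omega`). Stop-creating proposals are always rejected.
#'
#' @param n_codons Ancestral ORF length in codons (>= 30 recommended for
#'   stable dN/dS estimation).
#' @param subs_per_site Expected proposed mutations per nucleotide site per
#'   branch.
#' @param omega Target dN/dS.
#' @param ts_tv Transition/transversion proposal ratio (default 1, the
#'   Jukes-Cantor-like setting matching the downstream estimators).
#' @param seed Integer seed; the function is a pure function of its
#'   arguments.
#' @param ids Labels for the two descendants.
#' @return A [coding_pair()] with attributes `ancestor` and `realized`
#'   (accepted synonymous/nonsynonymous substitution counts per branch).
#' @export
simulate_ortholog_pair <- function(n_codons = 300, subs_per_site = 0.05,
                                   omega = 0.3, ts_tv = 1, seed = 1L,
                                   ids = c("a", "b")) {
  stopifnot(n_codons >= 2, omega >= 0, subs_per_site >= 0)
  withr::with_seed(seed, {
    anc <- random_orf(n_codons)
    n_prop <- rpois(2L, subs_per_site * 3 * n_codons)
    ba <- evolve_branch(anc, n_prop[1], omega, ts_tv)
    bb <- evolve_branch(anc, n_prop[2], omega, ts_tv)
    pair <- coding_pair(ba$nt, bb$nt, id_a = ids[1], id_b = ids[2])
    attr(pair, "ancestor") <- anc
    attr(pair, "realized") <- tibble::tibble(
      branch = ids,
      n_syn = c(ba$n_syn, bb$n_syn),
      n_nonsyn = c(ba$n_nonsyn, bb$n_nonsyn))
    pair
  })
}

#' Simulate dose-response plates from known logistic parameters
#'
#' Generates triplicate responses along a log-spaced concentration series
#' (default seven decades, 10 nM to 10 mM) from the 3-parameter logistic
#' model plus Gaussian noise scaled to each receptor's span, together with
#' a flat vector-control dataset.
#'
#' @param params Tibble with columns `receptor`, `odor`, `bottom`, `top`,
#'   `logec50` (true parameters per receptor x odor).
#' @param log10_conc Concentration series, log10 molar.
#' @param n_reps Replicates per concentration.
#' @param noise_frac Noise standard deviation as a fraction of each
#'   receptor's span (the control uses the set's maximum span).
#' @param noise `"gaussian"` (additive, default) or `"lognormal"`
#'   (multiplicative on positive expected responses).
#' @param seed Integer seed.
#' @return A tibble `receptor`, `odor`, `log10_conc_M`, `replicate`,
#'   `response`, including rows for receptor `"vector"` (the control);
#'   the true parameters are attached as attribute `truth`.
#' @export
simulate_dose_response <- function(params,
                                   log10_conc = seq(-8, -2, by = 1),
                                   n_reps = 3, noise_frac = 0.05,
                                   noise = c("gaussian", "lognormal"),
                                   seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n_reps >= 1, noise_frac >= 0)
  params <- tibble::as_tibble(params)
  spans <- params$top - params$bottom
  ctrl_sd <- noise_frac * max(abs(spans), 1e-12)
  withr::with_seed(seed, {
    one <- function(receptor, odor, bottom, top, logec50) {
      grid <- tidyr::expand_grid(log10_conc_M = log10_conc,
                                 replicate = seq_len(n_reps))
      mu <- logistic3(grid$log10_conc_M, bottom, top, logec50)
      sd_i <- ctrl_sd  # homoscedastic across the set: fraction of max span
      resp <- if (noise == "gaussian") {
        mu + rnorm(nrow(grid), 0, sd_i)
      } else {
        mu * exp(rnorm(nrow(grid), 0, sd_i / pmax(abs(mu), 1e-12)))
      }
      tibble::tibble(receptor = receptor, odor = odor,
                     log10_conc_M = grid$log10_conc_M,
                     replicate = grid$replicate, response = resp)
    }
    out <- purrr::pmap_dfr(params[c("receptor", "odor", "bottom", "top",
                                    "logec50")], one)
    ctrl_bottom <- mean(params$bottom)
    ctrl <- purrr::map_dfr(unique(params$odor), function(od) {
      grid <- tidyr::expand_grid(log10_conc_M = log10_conc,
                                 replicate = seq_len(n_reps))
      tibble::tibble(receptor = "vector", odor = od,
                     log10_conc_M = grid$log10_conc_M,
                     replicate = grid$replicate,
                     response = ctrl_bottom + rnorm(nrow(grid), 0, ctrl_sd))
    })
    res <- dplyr::bind_rows(out, ctrl)
    attr(res, "truth") <- params
    res
  })
}

#' Simulate a 42-odor luciferase screen
#'
#' Produces well-level plate measurements (firefly and Renilla readings)
#' for a set of receptors against an odor panel, with configured per-odor
#' effects on the firefly/Renilla ratio, triplicate Gaussian noise,
#' optional inhibitory (negative) effects, and no-odor plus vector-control
#' wells.
#'
#' @param receptors Character vector of receptor labels.
#' @param n_odors Panel size (default 42).
#' @param effects Optional tibble `receptor`, `odor`, `effect` giving the
#'   true shift of the firefly/Renilla ratio; if `NULL`, each receptor is
#'   assigned `n_active` agonists with geometrically decaying effect sizes
#'   and a fraction of inhibitory odors.
#' @param n_active Agonist odors per receptor when auto-generating effects.
#' @param effect_max Largest ratio shift for an agonist.
#' @param inhib_fraction Fraction of non-agonist odors given a negative
#'   effect.
#' @param baseline Basal firefly/Renilla ratio.
#' @param noise_sd Well-to-well Gaussian noise on the ratio.
#' @param n_reps Replicates per receptor x odor (default 3).
#' @param renilla_mean,renilla_cv Renilla luminescence level and
#'   coefficient of variation (the firefly reading is ratio times Renilla).
#' @param seed Integer seed.
#' @return Tibble `receptor`, `odor`, `replicate`, `firefly`, `renilla`,
#'   `plate_id` including `"no_odor"` columns and a `"vector"` control
#'   receptor; the true effects are attached as attribute `truth`.
#' @export
simulate_screen <- function(receptors, n_odors = 42, effects = NULL,
                            n_active = 6, effect_max = 1,
                            inhib_fraction = 0.05, baseline = 0.1,
                            noise_sd = 0.02, n_reps = 3,
                            renilla_mean = 100, renilla_cv = 0.1,
                            seed = 1L) {
  stopifnot(n_reps >= 2, noise_sd > 0)
  odors <- sprintf("odor%02d", seq_len(n_odors))
  withr::with_seed(seed, {
    if (is.null(effects)) {
      effects <- purrr::map_dfr(receptors, function(rec) {
        act <- sample(odors, min(n_active, n_odors))
        eff <- effect_max * exp(-0.4 * (seq_along(act) - 1))
        rest <- setdiff(odors, act)
        inhib <- rest[runif(length(rest)) < inhib_fraction]
        dplyr::bind_rows(
          tibble::tibble(receptor = rec, odor = act, effect = eff),
          tibble::tibble(receptor = rec, odor = inhib,
                         effect = -0.3 * effect_max))
      })
    }
    all_recs <- c(receptors, "vector")
    grid <- tidyr::expand_grid(receptor = all_recs,
                               odor = c(odors, "no_odor"),
                               replicate = seq_len(n_reps))
    grid <- dplyr::left_join(grid, effects, by = c("receptor", "odor"))
    grid$effect[is.na(grid$effect)] <- 0
    ratio <- baseline + grid$effect + rnorm(nrow(grid), 0, noise_sd)
    renilla <- renilla_mean * exp(rnorm(nrow(grid), 0,
                                        sqrt(log(1 + renilla_cv^2))))
    res <- tibble::tibble(
      receptor = grid$receptor, odor = grid$odor,
      replicate = grid$replicate,
      firefly = ratio * renilla, renilla = renilla,
      plate_id = "plate1")
    attr(res, "truth") <- effects
    res
  })
}

#' Simulate a blob-structured chemical descriptor space
#'
#' Gaussian blobs standing in for the physicochemical descriptor matrix of
#' a large odorant library, with known-active flags.
#'
#' @param n Number of odorants.
#' @param d Number of descriptors (default 20).
#' @param n_blobs Number of Gaussian clusters.
#' @param separation Between-center standard deviation relative to the
#'   unit within-blob spread.
#' @param active_frac Probability that an odorant is a known active.
#' @param seed Integer seed.
#' @return Tibble `id`, `active`, `d1`..`d<d>` with the generating blob
#'   index attached as attribute `blob`.
#' @export
simulate_descriptor_space <- function(n = 2683, d = 20, n_blobs = 42,
                                      separation = 6, active_frac = 0.1,
                                      seed = 1L) {
  stopifnot(n >= n_blobs, d >= 2)
  withr::with_seed(seed, {
    centers <- matrix(rnorm(n_blobs * d, 0, separation), n_blobs, d)
    blob <- sort(rep_len(seq_len(n_blobs), n))
    x <- centers[blob, , drop = FALSE] + matrix(rnorm(n * d), n, d)
    colnames(x) <- paste0("d", seq_len(d))
    res <- dplyr::bind_cols(
      tibble::tibble(id = sprintf("od%04d", seq_len(n)),
                     active = runif(n) < active_frac),
      tibble::as_tibble(x))
    attr(res, "blob") <- blob
    res
  })
}
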