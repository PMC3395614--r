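# End-to-end synthetic study: ortholog trios (plus optional paralogs) with
# coupled sequence and functional divergence, emitting every input the
# pipeline stages consume.

#' Provisional binding-site position set
#'
#' A synthetic stand-in for the 22 ligand-binding residue coordinates used
#' in binding-site Grantham comparisons: 22 positions spread evenly through
#' the amino-acid alignment. The experimentally motivated coordinates are
#' not re-derived here; supply your own set via [residue_positions()] when
#' available.
#'
#' @param n_aa Alignment length in residues.
#' @return A [residue_positions()] set of 22 positions labelled `"22AA"`.
#' @export
binding_positions_22aa <- function(n_aa) {
  stopifnot(n_aa >= 40)
  residue_positions(round(seq(10, n_aa - 9, length.out = 22)), label = "22AA")
}

#' Simulate a complete ortholog-function study
#'
#' Generates `n_sets` ortholog trios (reference species plus two variants,
#' mirroring a human/chimp/macaque design) with known ground truth at every
#' level: coding sequences diverged under a target dN/dS; a 42-odor screen
#' in which each variant's tuning profile is the reference profile
#' attenuated plus a perturbation whose size grows with the realized
#' nonsynonymous divergence of the pair (so sequence and functional
#' divergence are genuinely coupled); and dose-response plates for a common
#' ligand per set, where each comparison receptor responds with a
#' relationship-specific probability and responders draw shifted
#' potency/efficacy parameters. Optional paralogs evolve on a much longer
#' branch and respond at a lower rate.
#'
#' @param n_sets Number of ortholog sets.
#' @param n_odors Screen panel size.
#' @param n_codons ORF length per set.
#' @param omega Target dN/dS for ortholog branches.
#' @param divergences Proposed substitutions per site for the
#'   reference-variant1 split of each set (variant 2 evolves on a branch
#'   three times longer, giving the second species pair).
#' @param perturb_per_nonsyn Tuning-profile perturbation SD contributed per
#'   realized nonsynonymous substitution separating a pair.
#' @param ortholog_respond_rate,paralog_respond_rate Probability that a
#'   comparison receptor responds to the set's common ligand.
#' @param n_paralogs Paralogs per set (evolved at `paralog_divergence`).
#' @param paralog_divergence Proposed substitutions per site on a paralog
#'   branch.
#' @param noise_frac Dose-response noise SD as a fraction of the set span.
#' @param seed Integer seed; the study is a pure function of its arguments.
#' @return A list: `alignment` (named nt sequences), `pairs` (id_a, id_b,
#'   set, relationship, species_pair), `sets` (receptor-to-set map with
#'   reference flags), `screen` (plate wells), `dose` (dose-response rows
#'   incl. vector control), `truth` (per-receptor ground truth), and
#'   `positions` (provisional binding-site set).
#' @export
simulate_study <- function(n_sets = 12, n_odors = 42, n_codons = 310,
                           omega = 0.3,
                           divergences = seq(0.01, 0.08,
                                             length.out = n_sets),
                           perturb_per_nonsyn = 0.012,
                           ortholog_respond_rate = 0.82,
                           paralog_respond_rate = 0.33,
                           n_paralogs = 1,
                           paralog_divergence = 0.3,
                           noise_frac = 0.05,
                           seed = 1L) {
  stopifnot(length(divergences) == n_sets)
  withr::with_seed(seed, {
    odors <- sprintf("odor%02d", seq_len(n_odors))
    alignment <- character()
    pairs <- list()
    sets <- list()
    screen_effects <- list()
    dr_params <- list()
    truth <- list()

    for (i in seq_len(n_sets)) {
      set_id <- sprintf("set%02d", i)
      anc <- random_orf(n_codons)
      div <- divergences[i]
      branch_len <- c(ref = div / 2, v1 = div / 2, v2 = 1.5 * div)
      recs <- c(ref = sprintf("hOR%02d", i),
                v1 = sprintf("cOR%02d", i),
                v2 = sprintf("mOR%02d", i))
      evolved <- purrr::map(branch_len, function(bl) {
        evolve_branch(anc, rpois(1L, bl * 3 * n_codons), omega)
      })
      if (n_paralogs > 0) {
        for (p in seq_len(n_paralogs)) {
          role <- sprintf("para%d", p)
          recs[role] <- sprintf("pOR%02d_%d", i, p)
          evolved[[role]] <- evolve_branch(
            anc, rpois(1L, paralog_divergence * 3 * n_codons),
            omega)
        }
      }
      for (role in names(recs)) alignment[[recs[[role]]]] <- evolved[[role]]$nt

      roles <- names(recs)
      species_pair <- c(v1 = "human-chimp", v2 = "human-macaque")
      for (role in setdiff(roles, "ref")) {
        pairs[[length(pairs) + 1L]] <- tibble::tibble(
          id_a = recs[["ref"]], id_b = recs[[role]], set = set_id,
          relationship = if (startsWith(role, "v")) "ortholog" else "paralog",
          species_pair = if (startsWith(role, "v")) species_pair[[role]]
                         else "within-human")
      }

      # screen: variant profile = attenuated reference + divergence-coupled
      # perturbation; paralog profiles are drawn independently
      ref_active <- sample(odors, 6L)
      ref_eff <- setNames(rep(0, n_odors), odors)
      ref_eff[ref_active] <- exp(-0.4 * (0:5))
      inhib <- sample(setdiff(odors, ref_active), 2L)
      ref_eff[inhib] <- -0.3
      screen_effects[[recs[["ref"]]]] <- ref_eff
      nonsyn <- vapply(evolved, function(e) e$n_nonsyn, integer(1))
      for (role in setdiff(roles, "ref")) {
        rec <- recs[[role]]
        if (startsWith(role, "v")) {
          pair_nonsyn <- nonsyn[["ref"]] + nonsyn[[role]]
          atten <- runif(1, 0.4, 1)
          pert <- rnorm(n_odors, 0, perturb_per_nonsyn * pair_nonsyn)
          screen_effects[[rec]] <- atten * ref_eff + pert
        } else {
          eff <- setNames(rep(0, n_odors), odors)
          eff[sample(odors, 6L)] <- exp(-0.4 * (0:5)) * runif(1, 0.5, 1)
          screen_effects[[rec]] <- eff
        }
      }

      # dose-response for the set's common ligand
      common <- names(which.max(ref_eff))
      ref_logec50 <- runif(1, -6.5, -4.5)
      ref_span <- 1
      bottom <- 0.1
      dr_params[[recs[["ref"]]]] <- tibble::tibble(
        receptor = recs[["ref"]], odor = common, bottom = bottom,
        top = bottom + ref_span, logec50 = ref_logec50)
      for (role in setdiff(roles, "ref")) {
        rec <- recs[[role]]
        rate <- if (startsWith(role, "v")) ortholog_respond_rate
                else paralog_respond_rate
        responder <- runif(1) < rate
        if (responder) {
          lec <- ref_logec50 + rnorm(1, 0, 0.7)
          span <- ref_span * exp(rnorm(1, -0.3, 0.5))
        } else {
          lec <- NA_real_
          span <- 0
        }
        dr_params[[rec]] <- tibble::tibble(
          receptor = rec, odor = common, bottom = bottom,
          top = bottom + span,
          logec50 = if (responder) lec else -4.5)
        truth[[rec]] <- tibble::tibble(
          set = set_id, receptor = rec,
          relationship = if (startsWith(role, "v")) "ortholog" else "paralog",
          species_pair = if (startsWith(role, "v")) species_pair[[role]]
                         else "within-human",
          responder = responder, common_ligand = common,
          true_logec50 = lec, true_span = span,
          n_nonsyn_branch = nonsyn[[role]])
      }
      truth[[recs[["ref"]]]] <- tibble::tibble(
        set = set_id, receptor = recs[["ref"]], relationship = "reference",
        species_pair = NA_character_, responder = TRUE,
        common_ligand = common, true_logec50 = ref_logec50,
        true_span = ref_span, n_nonsyn_branch = nonsyn[["ref"]])
      sets[[set_id]] <- tibble::tibble(
        set = set_id, receptor = unname(recs),
        reference = unname(recs) == recs[["ref"]])
    }

    effects_tbl <- purrr::imap_dfr(screen_effects, function(eff, rec) {
      tibble::tibble(receptor = rec, odor = names(eff), effect = unname(eff))
    }) |> dplyr::filter(.data$effect != 0)
    screen <- simulate_screen(
      receptors = names(screen_effects), n_odors = n_odors,
      effects = effects_tbl, seed = sample.int(.Machine$integer.max, 1L))
    dose <- simulate_dose_response(
      dplyr::bind_rows(dr_params), noise_frac = noise_frac,
      seed = sample.int(.Machine$integer.max, 1L))

    list(alignment = alignment,
         pairs = dplyr::bind_rows(pairs),
         sets = dplyr::bind_rows(sets),
         screen = screen,
         dose = dose,
         truth = dplyr::bind_rows(truth),
         positions = binding_positions_22aa(n_codons))
  })
}
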