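# Stage orchestration: each stage reads tabular inputs, runs one module,
# writes tab-separated outputs whose header comment carries the digest of a
# JSON manifest (tool version, config, seeds, input digests, timestamp).

orevo_version <- function() {
  as.character(utils::packageVersion("orevo"))
}

file_digests <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  paths <- unlist(paths[vapply(paths, is.character, logical(1))])
  if (length(paths) == 0L) return(list())
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0L) return(list())
  as.list(tools::md5sum(paths))
}

new_manifest <- function(stage, config, inputs = character(), seed = NULL) {
  list(tool = "orevo", version = orevo_version(), stage = stage,
       config = config, seed = seed, inputs = file_digests(inputs),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

write_stage_tsv <- function(tbl, path, manifest) {
  mpath <- paste0(sub("\\.tsv$", "", path), ".manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  digest <- unname(tools::md5sum(mpath))
  writeLines(sprintf("# orevo %s manifest=%s", manifest$stage, digest), path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a stage output TSV
#'
#' Reads a tab-separated stage output, skipping the manifest header
#' comment.
#'
#' @param path Path to a `.tsv` written by a pipeline stage.
#' @return A tibble.
#' @export
read_stage_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

as_input_tbl <- function(x, reader = read_stage_tsv) {
  if (is.character(x) && length(x) == 1L) reader(x) else tibble::as_tibble(x)
}

#' Sequence stage: pairwise metrics table
#'
#' Reads a codon-aligned FASTA and a pair list, computes Jukes-Cantor,
#' Grantham (ORF and optional binding-site subset) and Nei-Gojobori
#' dN/dS/omega for every pair, and writes `seq_metrics.tsv`.
#'
#' @param fasta Path to an aligned nucleotide FASTA, or a named character
#'   vector of sequences.
#' @param pairs Path to a TSV (or a tibble) with columns `id_a`, `id_b`
#'   (extra annotation columns are carried through).
#' @param out_dir Output directory.
#' @param positions Optional [residue_positions()] for the binding-site
#'   Grantham column.
#' @return The metrics tibble (also written to disk).
#' @export
run_seq_stage <- function(fasta, pairs, out_dir, positions = NULL) {
  alignment <- if (is.character(fasta) && length(fasta) == 1L &&
                   file.exists(fasta)) read_alignment_fasta(fasta) else fasta
  pairs_tbl <- as_input_tbl(pairs)
  metrics <- pairwise_metrics(alignment, pairs_tbl[c("id_a", "id_b")],
                              positions = positions)
  extra <- dplyr::select(pairs_tbl, -dplyr::any_of(
    setdiff(names(metrics), c("id_a", "id_b"))))
  out <- dplyr::left_join(metrics, extra, by = c("id_a", "id_b"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- new_manifest(
    "seq", config = list(positions = as.integer(positions)),
    inputs = list(fasta = fasta, pairs = pairs))
  write_stage_tsv(out, file.path(out_dir, "seq_metrics.tsv"), manifest)
  out
}

#' Screen stage: normalized calls and tuning curves
#'
#' Normalizes the plate measurements, calls significant responses at the
#' Bonferroni-corrected level, and writes `screen_calls.tsv`. When a
#' receptor-set table is given, center-out tuning curves ordered by each
#' set's reference receptor are written to `tuning_curves.tsv`.
#'
#' @param plate Path to a plate CSV (`receptor`, `odor`, `replicate`,
#'   `firefly`, `renilla`, `plate_id`) or an equivalent tibble.
#' @param out_dir Output directory.
#' @param sets Optional tibble `set`, `receptor`, `reference` grouping
#'   receptors into ortholog sets.
#' @param scope,n_odors,alpha Passed to [normalize_plate()] /
#'   [call_agonists()].
#' @return A list with `calls` and (when sets are given) `tuning`.
#' @export
run_screen_stage <- function(plate, out_dir, sets = NULL,
                             scope = "plate_set", n_odors = 42,
                             alpha = 0.05) {
  plate_tbl <- as_input_tbl(plate, reader = function(p) {
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  })
  if (nrow(plate_tbl) == 0L ||
      all(plate_tbl$odor %in% c("no_odor", "vector"))) {
    orevo_abort("plate contains no odor wells", "orevo_plate_error")
  }
  screen <- normalize_plate(plate_tbl, scope = scope)
  calls <- call_agonists(screen, n_odors = n_odors, alpha = alpha)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- new_manifest(
    "screen",
    config = list(scope = scope, n_odors = n_odors, alpha = alpha),
    inputs = list(plate = plate))
  write_stage_tsv(calls, file.path(out_dir, "screen_calls.tsv"), manifest)
  tuning <- NULL
  if (!is.null(sets)) {
    sets <- as_input_tbl(sets)
    resp <- tuning_responses(calls)
    tuning <- sets |>
      dplyr::distinct(.data$set) |>
      dplyr::pull("set") |>
      purrr::map_dfr(function(s) {
        members <- sets$receptor[sets$set == s]
        refr <- sets$receptor[sets$set == s & sets$reference][1]
        sub <- dplyr::filter(resp, .data$receptor %in% members)
        tc <- order_tuning_curve(sub, reference = refr)
        dplyr::mutate(tibble::as_tibble(tc), set = s, .before = 1)
      })
    write_stage_tsv(tuning, file.path(out_dir, "tuning_curves.tsv"),
                    manifest)
  }
  list(calls = calls, tuning = tuning)
}

#' Dose-response stage: fits, gates, pair comparisons
#'
#' Fits every receptor x odor dose-response dataset, applies the agonist
#' gate against the matching vector-control wells, classifies every listed
#' receptor pair by the extra-sum-of-squares test, and writes `fits.tsv`,
#' `comparisons.tsv` and `classification_summary.tsv` (label fractions per
#' species pair).
#'
#' @param dose Path to a dose-response CSV (`receptor`, `odor`,
#'   `log10_conc_M`, `replicate`, `response`; receptor `"vector"` rows are
#'   the controls, matched by odor) or an equivalent tibble.
#' @param pairing Tibble (or TSV path) with `id_a`, `id_b` and optional
#'   `set`, `relationship`, `species_pair` columns.
#' @param out_dir Output directory.
#' @param alpha Significance level for gate and comparison.
#' @return A list with `fits`, `comparisons`, `summary`.
#' @export
run_dr_stage <- function(dose, pairing, out_dir, alpha = 0.05) {
  dose_tbl <- as_input_tbl(dose, reader = function(p) {
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  })
  pairing <- as_input_tbl(pairing)
  ds <- dplyr::filter(dose_tbl, .data$receptor != "vector")
  controls <- dplyr::filter(dose_tbl, .data$receptor == "vector")
  cells <- dplyr::distinct(ds, .data$receptor, .data$odor)

  fit_one <- function(receptor, odor) {
    d <- dplyr::filter(ds, .data$receptor == !!receptor,
                       .data$odor == !!odor)
    ctrl <- dplyr::filter(controls, .data$odor == !!odor)
    fit <- fit_3pl(d)
    gate <- agonist_gate(fit, d, ctrl, alpha = alpha)
    dplyr::bind_cols(
      tibble::tibble(receptor = receptor, odor = odor),
      glance(fit)[c("logec50", "se_logec50", "bottom", "top", "span",
                    "ss", "df")],
      tibble::tibble(agonist = gate$agonist,
                     reasons = paste(gate$reasons, collapse = ";")))
  }
  fits <- purrr::pmap_dfr(cells, fit_one)

  compare_one <- function(row) {
    odors_a <- ds$odor[ds$receptor == row$id_a]
    odors_b <- ds$odor[ds$receptor == row$id_b]
    odor <- intersect(odors_a, odors_b)[1]
    if (is.na(odor)) {
      return(dplyr::bind_cols(
        row, classification_row("not_comparable", NA, NA, NA, NA, NA, NA)))
    }
    da <- dplyr::filter(ds, .data$receptor == row$id_a, .data$odor == odor)
    db <- dplyr::filter(ds, .data$receptor == row$id_b, .data$odor == odor)
    ctrl <- dplyr::filter(controls, .data$odor == odor)
    cls <- classify_pair(da, db, control_a = ctrl, control_b = ctrl,
                         alpha = alpha)
    dplyr::bind_cols(row, odor = odor, cls)
  }
  comparisons <- if (nrow(pairing) == 0L) {
    dplyr::bind_cols(pairing,
                     classification_row("", 0, 0, 0, 0, 0, 0)[0, ])
  } else {
    pairing |>
      dplyr::rowwise() |>
      dplyr::group_split() |>
      purrr::map_dfr(compare_one)
  }

  summary <- comparisons |>
    dplyr::mutate(stratum = if ("species_pair" %in% names(comparisons)) {
      .data$species_pair
    } else {
      "all"
    }) |>
    dplyr::count(.data$stratum, .data$label) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- new_manifest("dose_response", config = list(alpha = alpha),
                           inputs = list(dose = dose))
  write_stage_tsv(fits, file.path(out_dir, "fits.tsv"), manifest)
  write_stage_tsv(comparisons, file.path(out_dir, "comparisons.tsv"),
                  manifest)
  write_stage_tsv(summary, file.path(out_dir, "classification_summary.tsv"),
                  manifest)
  list(fits = fits, comparisons = comparisons, summary = summary)
}

#' Comparison stage: sequence-function report
#'
#' Links the upstream tables: computes the functional distance (1 - R over
#' the zeroed screen profiles) per pair, Spearman correlations of each
#' sequence metric against functional distance, common-ligand response
#' rates by relationship and species pair (responder = passed the agonist
#' gate), Wilcoxon rank-sum comparisons of ortholog vs paralog Grantham
#' distributions, and omega distribution summaries.
#'
#' @param seq_metrics `seq_metrics.tsv` path or tibble ([run_seq_stage()]).
#' @param screen_calls `screen_calls.tsv` path or tibble.
#' @param fits `fits.tsv` path or tibble ([run_dr_stage()]).
#' @param pairing Pair table with `id_a`, `id_b`, `relationship`,
#'   `species_pair`.
#' @param out_dir Output directory.
#' @param min_responsive Responsiveness threshold for functional-distance
#'   inclusion.
#' @return A list: `seq_func`, `correlations`, `rates`, `ranksum`,
#'   `omega_summary`.
#' @export
run_compare_stage <- function(seq_metrics, screen_calls, fits, pairing,
                              out_dir, min_responsive = 3) {
  seq_tbl <- as_input_tbl(seq_metrics) |>
    dplyr::select(-dplyr::any_of(c("set", "relationship", "species_pair")))
  calls <- as_input_tbl(screen_calls)
  fits_tbl <- as_input_tbl(fits)
  pairing <- as_input_tbl(pairing)
  if (nrow(seq_tbl) == 0L || nrow(calls) == 0L) {
    orevo_abort("empty input table(s) for the comparison stage",
                "orevo_stat_error")
  }

  resp <- calls |>
    dplyr::mutate(response = ifelse(.data$significant,
                                    .data$mean_response, 0)) |>
    dplyr::filter(.data$receptor != "vector") |>
    dplyr::arrange(.data$odor)
  profile <- function(rec) {
    r <- dplyr::filter(resp, .data$receptor == rec)
    setNames(r$response, r$odor)
  }
  fd <- purrr::map2_dfr(pairing$id_a, pairing$id_b, function(a, b) {
    pa <- profile(a)
    pb <- profile(b)
    stopifnot(identical(names(pa), names(pb)))
    dplyr::bind_cols(tibble::tibble(id_a = a, id_b = b),
                     functional_distance(pa, pb,
                                         min_responsive = min_responsive))
  })
  sf <- seq_func_table(seq_tbl, dplyr::filter(fd, .data$included)) |>
    dplyr::left_join(pairing[c("id_a", "id_b", "relationship",
                               "species_pair")],
                     by = c("id_a", "id_b"))

  orth <- dplyr::filter(sf, .data$relationship == "ortholog",
                        !is.na(.data$functional_distance))
  correlations <- purrr::map_dfr(
    c("jc", "grantham_orf", "grantham_22aa", "omega"),
    function(mtr) {
      ok <- !is.na(orth[[mtr]])
      res <- if (sum(ok) >= 4) {
        rank_correlation(orth[[mtr]][ok], orth$functional_distance[ok])
      } else {
        tibble::tibble(rho = NA_real_, p = NA_real_, n = sum(ok),
                       defined = FALSE)
      }
      dplyr::bind_cols(tibble::tibble(metric = mtr), res)
    })

  responders <- fits_tbl |>
    dplyr::select(id_b = "receptor", responder = "agonist") |>
    dplyr::inner_join(pairing, by = "id_b")
  rates <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(stratum = "ortholog"),
                     common_ligand_rate(responders,
                                        relationship = "ortholog")),
    dplyr::bind_cols(tibble::tibble(stratum = "paralog"),
                     common_ligand_rate(responders,
                                        relationship = "paralog")),
    purrr::map_dfr(
      unique(stats::na.omit(responders$species_pair[
        responders$relationship == "ortholog"])),
      function(sp) {
        dplyr::bind_cols(tibble::tibble(stratum = sp),
                         common_ligand_rate(responders, species_pair = sp))
      }))

  seq_rel <- dplyr::left_join(
    seq_tbl, pairing[c("id_a", "id_b", "relationship")],
    by = c("id_a", "id_b"))
  ranksum <- purrr::map_dfr(c("grantham_orf", "grantham_22aa"),
    function(mtr) {
      a <- seq_rel[[mtr]][seq_rel$relationship == "ortholog"]
      b <- seq_rel[[mtr]][seq_rel$relationship == "paralog"]
      res <- if (sum(!is.na(a)) >= 3 && sum(!is.na(b)) >= 3) {
        ranksum_compare(a, b)
      } else {
        tibble::tibble(z = NA_real_, p = NA_real_, w = NA_real_,
                       n_a = sum(!is.na(a)), n_b = sum(!is.na(b)),
                       defined = FALSE)
      }
      dplyr::bind_cols(tibble::tibble(metric = mtr,
                                      group_a = "ortholog",
                                      group_b = "paralog"), res)
    })

  omega_summary <- seq_rel |>
    dplyr::filter(.data$relationship == "ortholog", !is.na(.data$omega)) |>
    (\(d) if (nrow(d) == 0L) tibble::tibble() else {
      summarize_distribution(d$omega)
    })()

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- new_manifest(
    "compare", config = list(min_responsive = min_responsive),
    inputs = list(seq_metrics = seq_metrics, screen_calls = screen_calls,
                  fits = fits))
  write_stage_tsv(sf, file.path(out_dir, "seq_func.tsv"), manifest)
  write_stage_tsv(correlations, file.path(out_dir, "correlations.tsv"),
                  manifest)
  write_stage_tsv(rates, file.path(out_dir, "rates.tsv"), manifest)
  write_stage_tsv(ranksum, file.path(out_dir, "ranksum.tsv"), manifest)
  if (nrow(omega_summary) > 0L) {
    write_stage_tsv(omega_summary, file.path(out_dir, "omega_summary.tsv"),
                    manifest)
  }
  list(seq_func = sf, correlations = correlations, rates = rates,
       ranksum = ranksum, omega_summary = omega_summary)
}

#' Run the full synthetic study end to end
#'
#' Simulates a complete study ([simulate_study()]), writes every input
#' file (FASTA alignment, pair/set tables, plate CSV, dose-response CSV),
#' runs the sequence, screen, dose-response and comparison stages in
#' order, and writes a run manifest. Stage outputs are identical to
#' running the stages individually on the same files.
#'
#' @param out_dir Output directory (inputs under `inputs/`, stage outputs
#'   under `stages/`).
#' @param seed Integer seed for the whole study.
#' @param ... Passed to [simulate_study()].
#' @param alpha Significance level for screen calls and comparisons.
#' @return A list: `sim` (ground truth), `seq`, `screen`, `dr`, `compare`.
#' @export
run_study <- function(out_dir, seed = 1L, ..., alpha = 0.05) {
  dir.create(file.path(out_dir, "inputs"), recursive = TRUE,
             showWarnings = FALSE)
  sim <- simulate_study(seed = seed, ...)
  paths <- list(
    fasta = file.path(out_dir, "inputs", "alignment.fasta"),
    pairs = file.path(out_dir, "inputs", "pairs.tsv"),
    sets = file.path(out_dir, "inputs", "sets.tsv"),
    plate = file.path(out_dir, "inputs", "plate.csv"),
    dose = file.path(out_dir, "inputs", "dose.csv"))
  write_alignment_fasta(sim$alignment, paths$fasta)
  readr::write_tsv(sim$pairs, paths$pairs)
  readr::write_tsv(sim$sets, paths$sets)
  readr::write_csv(sim$screen, paths$plate)
  readr::write_csv(sim$dose, paths$dose)

  stage_dir <- file.path(out_dir, "stages")
  seq_out <- run_seq_stage(paths$fasta, paths$pairs, stage_dir,
                           positions = sim$positions)
  screen_out <- run_screen_stage(paths$plate, stage_dir, sets = paths$sets,
                                 alpha = alpha)
  dr_out <- run_dr_stage(paths$dose, sim$pairs, stage_dir, alpha = alpha)
  cmp_out <- run_compare_stage(
    file.path(stage_dir, "seq_metrics.tsv"),
    file.path(stage_dir, "screen_calls.tsv"),
    file.path(stage_dir, "fits.tsv"),
    sim$pairs, stage_dir)

  manifest <- new_manifest("run_all", config = list(alpha = alpha,
                                                    args = list(...)),
                           inputs = paths, seed = seed)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  list(sim = sim, seq = seq_out, screen = screen_out, dr = dr_out,
       compare = cmp_out)
}
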