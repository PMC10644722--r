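# Pipeline commands tying the stages together:
#   simulate -> screen -> kinetics -> chemspace -> sasmap
# Each command reads the interchange CSVs, runs the corresponding module,
# and writes tables/JSON with a config-echo header. These functions are the
# programmatic surface behind the inst/cli/inhibscreen.R front end.

#' Generate a full set of synthetic pipeline inputs
#'
#' Writes a synthetic assay table (one dose-response experiment per library
#' compound), an initial-velocity kinetics table, and a compound table with
#' per-compound pIC50, all derived from one seed.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master RNG seed; per-stage seeds are derived from it.
#' @param n_scaffolds,per_scaffold library design, see [library_truth()].
#' @param kinetics_truth a [kinetic_truth()]; default is a non-competitive
#'   truth (VMAX 44.1 mM/min, KM 0.2 mM, KIcu 0.009 mM) on the default
#'   design with 5 percent noise.
#' @param noise_cv noise level for the dose-response tables.
#' @return invisibly, a named list of the written file paths.
#' @export
run_simulate <- function(out_dir, seed = 1, n_scaffolds = 3, per_scaffold = 8,
                         kinetics_truth = NULL, noise_cv = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lib <- gen_library(library_truth(n_scaffolds, per_scaffold, seed = seed))

  # assay table: absorbance pairs consistent with each compound's true pIC50
  conc <- c(2, 5, 10, 20, 50, 100, 250, 500)
  assay <- do.call(rbind, lapply(seq_len(nrow(lib)), function(k) {
    ic50 <- from_pic50(lib$pic50[k])
    dr <- gen_dose_response(
      dose_response_truth(ic50, hill = 1, noise_cv = noise_cv,
                          seed = seed + 1000 + k),
      conc, replicates = 3)
    # invert percent inhibition into absorbance changes against a fixed blank
    da_blank <- 0.5
    da_sample <- (1 - dr$inhibition / 100) * da_blank
    data.frame(compound_id = lib$compound_id[k], conc_uM = dr$concentration,
               a405_t0_sample = 0.05, a405_t20_sample = 0.05 + da_sample,
               a405_t0_blank = 0.05, a405_t20_blank = 0.05 + da_blank,
               replicate = dr$replicate)
  }))

  if (is.null(kinetics_truth)) {
    kinetics_truth <- kinetic_truth("linear_noncompetitive", vmax = 44.1,
                                    km = 0.2, constants = c(KIcu = 0.009),
                                    noise_cv = 0.05, replicates = 3,
                                    seed = seed + 2000)
  }
  kin <- gen_kinetic_dataset(kinetics_truth)

  paths <- list(
    assay = file.path(out_dir, "assay.csv"),
    kinetics = file.path(out_dir, "kinetics.csv"),
    compounds = file.path(out_dir, "compounds.csv"),
    smiles = file.path(out_dir, "library.smi")
  )
  write_table_csv(assay, paths$assay, seed = seed)
  write_table_csv(data.frame(s_mM = kin$s, i_mM = kin$i, v0 = kin$v0,
                             replicate = kin$replicate),
                  paths$kinetics, seed = seed)
  write_table_csv(lib, paths$compounds, seed = seed)
  write_smiles_file(lib, paths$smiles)
  message("simulate: wrote ", nrow(assay), " assay rows, ", nrow(kin),
          " kinetic points, ", nrow(lib), " compounds")
  invisible(paths)
}

#' Run the screening stage
#'
#' Percent inhibition per row, triage at the screening concentration, a
#' concentration-response fit per compound, and potency banding; writes a
#' potency table.
#'
#' @param assay input assay CSV path or data.frame (see [read_assay_csv()]).
#' @param out_dir output directory.
#' @param reference_pic50 reference compound pIC50 for activity differences
#'   (`NA` skips the column).
#' @param triage_conc screening concentration in uM (default 20).
#' @return the potency table (also written to `potency.csv`), with columns
#'   `compound_id`, `triage_pass`, `ic50_uM`, `pic50`, `delta_activity`,
#'   `band`, `converged`, `reduced_chi2`.
#' @export
run_screen <- function(assay, out_dir = NULL, reference_pic50 = NA,
                       triage_conc = 20) {
  df <- if (is.character(assay)) read_assay_csv(assay) else assay
  check_columns(df, .ASSAY_COLS, "assay table")
  df$inhibition <- percent_inhibition(df$a405_t0_sample, df$a405_t20_sample,
                                      df$a405_t0_blank, df$a405_t20_blank)
  res <- do.call(rbind, lapply(split(df, df$compound_id), function(d) {
    at_screen <- d$inhibition[d$conc_uM == triage_conc]
    pass <- if (length(at_screen) > 0) triage_screen(at_screen) else NA
    fit <- tryCatch(
      fit_dose_response(data.frame(concentration = d$conc_uM,
                                   inhibition = d$inhibition)),
      error = function(e) NULL)
    data.frame(
      compound_id = d$compound_id[1],
      triage_pass = pass,
      ic50_uM = if (!is.null(fit) && fit$converged) fit$ic50 else NA_real_,
      pic50 = if (!is.null(fit) && fit$converged) fit$pic50 else NA_real_,
      band = if (!is.null(fit) && fit$converged) classify_activity(fit$ic50)
             else NA_character_,
      converged = !is.null(fit) && fit$converged,
      reduced_chi2 = if (!is.null(fit)) fit$reduced_chi2 else NA_real_
    )
  }))
  rownames(res) <- NULL
  res$delta_activity <- if (is.finite(reference_pic50)) {
    ifelse(is.na(res$pic50), NA_real_, delta_activity(reference_pic50, res$pic50))
  } else NA_real_
  res <- res[, c("compound_id", "triage_pass", "ic50_uM", "pic50",
                 "delta_activity", "band", "converged", "reduced_chi2")]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_csv(res, file.path(out_dir, "potency.csv"),
                    config = list(reference_pic50 = reference_pic50,
                                  triage_conc = triage_conc))
  }
  message("screen: ", nrow(res), " compounds, ",
          sum(res$band == "hit", na.rm = TRUE), " hits")
  res
}

#' Run the kinetics stage
#'
#' Fits all seven mechanisms globally, writes the per-mechanism fits and the
#' selection report as JSON plus a double-reciprocal series CSV.
#'
#' @param kinetics input kinetics CSV path or [kinetic_dataset()].
#' @param out_dir output directory.
#' @param weights,n_starts passed to [select_mechanism()].
#' @return the `mechanism_selection` object.
#' @export
run_kinetics <- function(kinetics, out_dir = NULL, weights = "none",
                         n_starts = 5) {
  data <- if (is.character(kinetics)) read_kinetics_csv(kinetics)
          else kinetic_dataset(as.data.frame(kinetics))
  if (!any(data$i == 0)) {
    warning("no uninhibited (i = 0) series: VMAX/KM weakly identified",
            call. = FALSE)
  }
  sel <- select_mechanism(data, weights = weights, n_starts = n_starts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    report <- list(
      winner = sel$winner,
      rationale = sel$rationale,
      fits = lapply(sel$fits, function(f) list(
        mechanism = f$mechanism$label, converged = f$converged,
        params = as.list(f$params), standard_errors = as.list(f$uncertainties),
        reduced_chi2 = f$reduced_chi2))
    )
    jsonlite::write_json(report, file.path(out_dir, "kinetics_fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_table_csv(reciprocal_series(data),
                    file.path(out_dir, "reciprocal_series.csv"))
  }
  message("kinetics: winner ", sel$winner)
  sel
}

#' Run the chemical space stage
#'
#' Computes every fingerprint in the panel, ranks them by TSD area, and
#' projects the winning fingerprint with t-SNE.
#'
#' @param compounds compound CSV path or data.frame (`compound_id`, `smiles`).
#' @param out_dir output directory.
#' @param panel fingerprint names to compare (default: the full panel).
#' @param config an [embedding_config()]; its perplexity is lowered
#'   automatically to `floor((n - 1) / 3)` when the library is too small for
#'   the default of 40.
#' @return list with `selection` (`fp_selection`), `coordinates`
#'   (data.frame), `fp_name` used for the projection.
#' @export
run_chemspace <- function(compounds, out_dir = NULL,
                          panel = fingerprint_names(),
                          config = embedding_config()) {
  recs <- if (is.character(compounds)) read_compounds_csv(compounds)
          else compounds
  fsets <- lapply(panel, function(fp) compute_fingerprints(recs, fp))
  names(fsets) <- panel
  curves <- lapply(panel, function(fp) {
    tsd_curve(similarity_matrix(fsets[[fp]]), fp_name = fp)
  })
  names(curves) <- panel
  sel <- select_fingerprint(curves)
  n <- nrow(recs)
  if (config$perplexity >= n) {
    config$perplexity <- max(2, floor((n - 1) / 3))
    message("chemspace: perplexity lowered to ", config$perplexity,
            " for n = ", n)
  }
  coords <- project_chemspace(fsets[[sel$winner]], config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_csv(sel$ranking, file.path(out_dir, "fingerprint_ranking.csv"))
    write_table_csv(coords, file.path(out_dir, "chemspace_coords.csv"),
                    seed = config$seed,
                    config = list(fp_name = sel$winner,
                                  perplexity = config$perplexity,
                                  iterations = config$iterations))
  }
  message("chemspace: fingerprint ", sel$winner, ", ", n, " compounds")
  list(selection = sel, coordinates = coords, fp_name = sel$winner)
}

#' Run the SAS-map stage
#'
#' Fingerprints, similarity matrix, SAS map, and hop/analog/cliff reports.
#'
#' @param compounds compound CSV path or data.frame (`compound_id`, `smiles`,
#'   `pic50`).
#' @param out_dir output directory.
#' @param fp_name fingerprint to use (default `fp2_path`).
#' @param thresholds a [zone_thresholds()].
#' @param mode `"all_pairs"` (zone counting) or `"reference"`.
#' @param reference_id anchor compound for hops/analogs; defaults to the
#'   most potent compound when needed.
#' @return the `sas_map` object, with `hops`, `analogs`, `cliffs` attached.
#' @export
run_sasmap <- function(compounds, out_dir = NULL, fp_name = "fp2_path",
                       thresholds = zone_thresholds(),
                       mode = "all_pairs", reference_id = NULL) {
  recs <- if (is.character(compounds)) read_compounds_csv(compounds)
          else compounds
  check_columns(recs, .COMPOUND_COLS, "compound table")
  fps <- compute_fingerprints(recs, fp_name)
  sim <- similarity_matrix(fps)
  if (is.null(reference_id)) {
    reference_id <- recs$compound_id[which.max(recs$pic50)]
  }
  map <- build_sas_map(recs, sim, thresholds = thresholds, mode = mode,
                       reference_id = reference_id)
  map$hops <- scaffold_hops(map, reference_id)
  map$analogs <- true_analogs(map, reference_id)
  map$cliffs <- activity_cliffs(map)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg <- list(fp_name = fp_name, mode = mode, reference_id = reference_id,
                s_low_high = map$thresholds$s_low_high,
                a_low_high = map$thresholds$a_low_high)
    write_table_csv(map$pairs, file.path(out_dir, "sas_pairs.csv"), config = cfg)
    jsonlite::write_json(as.list(map$zone_counts),
                         file.path(out_dir, "zone_counts.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report <- data.frame(
      kind = c(rep("scaffold_hop", length(map$hops)),
               rep("true_analog", length(map$analogs))),
      compound_id = c(map$hops, map$analogs))
    write_table_csv(report, file.path(out_dir, "hops_analogs.csv"), config = cfg)
    write_table_csv(map$cliffs, file.path(out_dir, "activity_cliffs.csv"),
                    config = cfg)
  }
  message("sasmap: ", nrow(map$pairs), " pairs; zone counts ",
          paste(names(map$zone_counts), map$zone_counts, sep = "=",
                collapse = " "))
  map
}
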