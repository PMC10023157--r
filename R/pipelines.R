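# Orchestration of the two analyses: repeat/condensate association and PRE
# validation. Report bundles are plain-text TSV/JSON with no timestamps, so
# a rerun with the same configuration and seed is byte-identical.

#' Configuration for the report pipelines
#'
#' Collects the input paths, thresholds and seeds of a full run. Defaults
#' follow the analysis conventions used throughout the package: family-wise
#' alpha 0.05, Bonferroni-adjusted threshold 0.025 for the paired
#' contingency/rank comparisons, 20-residue composition windows at a 0.40
#' threshold, 50 size-matched resampling replicates.
#'
#' @param fasta,annotations,condensates Input paths for ingestion (the
#'   condensate argument is a character vector of list files); alternatively
#'   supply `protein_table` (a path to a serialized table or a data.frame).
#' @param protein_table Optional pre-built protein table (path or
#'   data.frame); overrides the raw inputs.
#' @param motifs Motif selection for the association screen (`"all"` or a
#'   character vector).
#' @param convention k-mer counting convention (`"tiling"` or `"runs"`).
#' @param eps_form Population-error form (`"sqrt"` or `"linear"`).
#' @param alpha Correlation-screen significance level.
#' @param bonferroni_m Number of paired comparisons for the adjusted
#'   threshold (default 2, giving 0.025).
#' @param composition_window,composition_threshold Composition-scan window
#'   length and minimum fraction.
#' @param resample_motif Motif submitted to size-matched resampling
#'   (default `"RS"`).
#' @param n_resample Number of resampling replicates.
#' @param seed Integer seed for every stochastic step (required when
#'   resampling is enabled).
#' @param reviewed_only,evidence_only Ingestion filters.
#' @param constants [pre_constants()] object (PRE pipeline only).
#' @param ensemble,decays PRE pipeline inputs: multi-model PDB and decay CSV.
#' @param fit_method Gamma2 estimator (`"two_point"` or `"lsq"`).
#' @return Named list of class `repeatsep_config`.
#' @export
run_config <- function(fasta = NULL, annotations = NULL, condensates = NULL,
                       protein_table = NULL, motifs = "all",
                       convention = "tiling", eps_form = "sqrt",
                       alpha = 0.05, bonferroni_m = 2L,
                       composition_window = 20L,
                       composition_threshold = 0.40,
                       resample_motif = "RS", n_resample = 50L, seed = NULL,
                       reviewed_only = TRUE, evidence_only = TRUE,
                       constants = NULL, ensemble = NULL, decays = NULL,
                       fit_method = "two_point") {
  structure(as.list(environment()), class = "repeatsep_config")
}

resolve_protein_table <- function(config) {
  if (!is.null(config$protein_table)) {
    if (is.data.frame(config$protein_table)) return(config$protein_table)
    return(read_protein_table(config$protein_table))
  }
  if (is.null(config$fasta)) stop("config supplies neither fasta nor protein_table")
  fasta <- read_protein_fasta(config$fasta)
  ann <- if (!is.null(config$annotations)) parse_annotations(config$annotations)
  cond <- if (!is.null(config$condensates))
    load_condensate_lists(config$condensates)
  build_protein_table(fasta, ann, cond,
                      reviewed_only = config$reviewed_only,
                      evidence_only = config$evidence_only)
}

config_json <- function(config) {
  cfg <- config
  cfg$protein_table <- if (is.data.frame(cfg$protein_table))
    "<in-memory protein table>" else cfg$protein_table
  cfg$constants <- if (!is.null(cfg$constants)) unclass(cfg$constants)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  c(list(tool = "repeatsep",
         version = as.character(utils::packageVersion("repeatsep"))), cfg)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the repeat/condensate association pipeline
#'
#' Ingest -> scan -> associate. Writes to `out_dir`:
#' `protein_table.tsv`, `scans.tsv`, `association.tsv` (per-motif screen),
#' `significant_motifs.txt`, `contingency.json` (Fisher's exact analyses of
#' repeat presence against RRM occurrence, stratified by condensate status,
#' plus rank tests on repeat-unit counts and the composition-window
#' analysis), `resampling.tsv` (size-matched replicates for
#' `config$resample_motif`), and `run_config.json`. Stage-level record
#' counts are reported via `message()`.
#'
#' @param config [run_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`proteins`,
#'   `scans`, `association`, `significant`, `contingency`, `resampling`).
#' @export
run_association_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "repeatsep_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  proteins <- resolve_protein_table(config)
  message("ingest: ", nrow(proteins), " proteins (",
          sum(proteins$in_condensate), " in condensates, ",
          sum(proteins$rrm_count > 0), " with RRM annotations, ",
          sum(proteins$rrm_count), " RRM domains)")
  scans <- scan_proteins(proteins, motifs = "all",
                         convention = config$convention)
  message("scan: ", nrow(scans), " protein-motif run summaries")
  assoc <- motif_association_screen(scans, proteins, motifs = config$motifs,
                                    eps_form = config$eps_form,
                                    alpha = config$alpha)
  significant <- assoc$motif[assoc$significant]
  message("associate: ", length(significant), " significant motif(s): ",
          paste(significant, collapse = ", "))

  # contingency analyses: repeat presence (longest RS-type run >= 4) against
  # RRM occurrence, stratified by condensate status, and against condensate
  # membership overall; plus rank tests on repeat unit counts and the
  # composition-window analysis
  rs_motif <- normalize_motif(config$resample_motif)
  L <- longest_runs_for_motif(scans, proteins$accession, rs_motif)
  has_rep <- L >= 4L
  has_rrm <- proteins$rrm_count > 0L
  ps <- proteins$in_condensate
  tab_ps <- table(factor(has_rep[ps], c(FALSE, TRUE)),
                  factor(has_rrm[ps], c(FALSE, TRUE)))
  tab_np <- table(factor(has_rep[!ps], c(FALSE, TRUE)),
                  factor(has_rrm[!ps], c(FALSE, TRUE)))
  tab_all <- table(factor(has_rep, c(FALSE, TRUE)),
                   factor(ps, c(FALSE, TRUE)))
  scans_rs <- scans[scans$motif == rs_motif, , drop = FALSE]
  u2 <- u4 <- stats::setNames(integer(nrow(proteins)), proteins$accession)
  idx <- match(scans_rs$accession, proteins$accession)
  u2[idx] <- scans_rs$unit_count_2
  u4[idx] <- scans_rs$unit_count_4
  mw <- list(
    unit2 = if (any(ps) && any(!ps)) mann_whitney(u2[ps], u2[!ps]),
    unit4 = if (any(ps) && any(!ps)) mann_whitney(u4[ps], u4[!ps]))
  comp <- vapply(proteins$sequence, function(s) {
    h <- suppressWarnings(
      composition_windows(s, window = config$composition_window,
                          threshold = config$composition_threshold))
    !is.null(h)
  }, logical(1))
  tab_comp <- table(factor(comp, c(FALSE, TRUE)), factor(ps, c(FALSE, TRUE)))
  contingency <- list(
    motif = rs_motif,
    bonferroni_threshold = bonferroni(config$alpha, config$bonferroni_m),
    repeat4_vs_rrm_in_condensates = list(
      table = unclass(tab_ps), p = fisher_exact(tab_ps)),
    repeat4_vs_rrm_not_in_condensates = list(
      table = unclass(tab_np), p = fisher_exact(tab_np)),
    repeat4_vs_condensate = list(
      table = unclass(tab_all), p = fisher_exact(tab_all)),
    composition_vs_condensate = list(
      window = config$composition_window,
      threshold = config$composition_threshold,
      table = unclass(tab_comp), p = fisher_exact(tab_comp),
      f_ps_without_hit = mean(ps[!comp]), f_ps_with_hit = mean(ps[comp])),
    mann_whitney_unit_counts = mw)

  resampling <- NULL
  if (!is.null(config$n_resample) && config$n_resample > 0L) {
    if (is.null(config$seed)) stop("config$seed is required for resampling")
    resampling <- size_matched_resample(L, ps,
                                        n_subsets = config$n_resample,
                                        seed = config$seed,
                                        eps_form = config$eps_form,
                                        alpha = config$alpha)
    message("resample: ", config$n_resample, " replicates, significant fraction ",
            format(attr(resampling, "significant_fraction")))
  }

  write_protein_table(proteins, file.path(out_dir, "protein_table.tsv"))
  write_tsv(scans, file.path(out_dir, "scans.tsv"))
  write_tsv(assoc, file.path(out_dir, "association.tsv"))
  writeLines(significant, file.path(out_dir, "significant_motifs.txt"))
  jsonlite::write_json(contingency, file.path(out_dir, "contingency.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(resampling))
    write_tsv(resampling, file.path(out_dir, "resampling.tsv"))
  jsonlite::write_json(config_json(config),
                       file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(proteins = proteins, scans = scans, association = assoc,
                 significant = significant, contingency = contingency,
                 resampling = resampling))
}

#' Run the PRE validation pipeline
#'
#' Fits observed Gamma2 from decay series, classifies residues, back-
#' calculates Gamma2 from the ensemble, and validates. Writes `profile.tsv`
#' (`residue`, `gamma2_obs`, `gamma2_err`, `gamma2_calc`, `flag`),
#' `metrics.json` (`Q`, `R`, `n`) and `run_config.json` to `out_dir`.
#'
#' @param config [run_config()] with `ensemble`, `decays` and `constants`
#'   set (the correlation time must be supplied via `constants`).
#' @param out_dir Output directory.
#' @return Invisibly, a list with `profile` and `metrics`.
#' @export
run_pre_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "repeatsep_config"))
  if (is.null(config$constants))
    stop("config$constants is required; construct it with pre_constants() ",
         "supplying tau_c (the PRE correlation time)")
  if (is.null(config$ensemble) || is.null(config$decays))
    stop("config must supply both ensemble (PDB) and decays (CSV)")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ens <- read_pre_ensemble(config$ensemble)
  calc <- ensemble_gamma2(ens, config$constants)
  decays <- read_decay_series(config$decays)
  obs <- fit_decay_table(decays, method = config$fit_method)
  message("pre: ", ens$n_models, " ensemble members, ", nrow(obs),
          " residues (", sum(obs$flag == "ok"), " ok, ",
          sum(obs$flag == "bleached"), " bleached, ",
          sum(obs$flag == "noisy"), " noisy, ",
          sum(obs$flag == "excluded"), " excluded)")
  profile <- merge(obs, calc[, c("residue", "gamma2_calc")],
                   by = "residue", all.x = TRUE)
  metrics <- pre_validate(obs, calc)
  write_tsv(profile, file.path(out_dir, "profile.tsv"))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(config_json(config),
                       file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(profile = profile, metrics = metrics))
}
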