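# Synthetic labelled proteomes and PRE observables with the statistical
# structure the analysis assumes, so every pipeline stage runs with no
# downloads.

#' Specification of a synthetic labelled proteome
#'
#' Describes a proteome in which the probability that a protein is labelled
#' as condensate-resident follows a logistic model in the length of its
#' planted repeat run and the presence of an RRM domain:
#' `P(label) = plogis(beta0 + beta1 * planted_run_length + beta2 * has_rrm)`.
#' The logistic link is the simplest monotone model reproducing a condensate
#' likelihood that increases with repeat length; the coefficients are fixture
#' parameters, not estimates.
#'
#' @param n_proteins Number of proteins (default 2000).
#' @param length_range Min/max sequence length, uniform (default 100-600).
#' @param background_freqs Named residue frequencies for the background
#'   sequence (default uniform over the 20 canonical residues).
#' @param motif Planted unordered dipeptide motif (default `"RS"`).
#' @param run_length_probs Named probability vector over planted longest-run
#'   lengths `{0, 2, 4, 6, 8, 10, 16}`. The default places about half the
#'   proteome in the no-repeat class with a tail of long repeats thick
#'   enough to populate the x >= 8 category.
#' @param rrm_prevalence Probability a protein carries an RRM annotation
#'   (default 0.1).
#' @param beta0,beta1,beta2 Label-model coefficients: baseline log-odds
#'   (default -1.5), per-residue effect of the planted run length (default
#'   0.25) and RRM effect (default 1.0). Set `beta1 = beta2 = 0` for a null
#'   proteome whose labels are independent of sequence.
#' @return Object of class `proteome_sim_spec`.
#' @export
proteome_sim_spec <- function(n_proteins = 2000L,
                              length_range = c(100L, 600L),
                              background_freqs = NULL,
                              motif = "RS",
                              run_length_probs = c("0" = 0.50, "2" = 0.15,
                                                   "4" = 0.12, "6" = 0.09,
                                                   "8" = 0.07, "10" = 0.04,
                                                   "16" = 0.03),
                              rrm_prevalence = 0.1,
                              beta0 = -1.5, beta1 = 0.25, beta2 = 1.0) {
  if (is.null(background_freqs))
    background_freqs <- stats::setNames(rep(1 / 20, 20), CANONICAL_AA)
  stopifnot(n_proteins >= 1L, length_range[1L] >= 4L,
            length_range[2L] >= length_range[1L],
            abs(sum(run_length_probs) - 1) < 1e-8,
            all(run_length_probs >= 0),
            rrm_prevalence >= 0, rrm_prevalence <= 1)
  motif <- normalize_motif(motif)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 background_freqs = background_freqs, motif = motif,
                 run_length_probs = run_length_probs,
                 rrm_prevalence = rrm_prevalence,
                 beta0 = beta0, beta1 = beta1, beta2 = beta2),
            class = "proteome_sim_spec")
}

# Alternating run of the motif's residues, starting with either residue at
# random (exercising the rule that counting starts at the first residue of a
# run, whichever of the two it is). Homo-pair motifs give mono-residue runs.
planted_run <- function(motif, len) {
  m <- strsplit(motif, "")[[1L]]
  if (m[1L] == m[2L]) return(strrep(m[1L], len))
  first <- sample(1:2, 1L)
  paste(rep(m, length.out = len + first - 1L)[first:(first + len - 1L)],
        collapse = "")
}

#' Generate a synthetic labelled proteome
#'
#' Draws sequences from the background composition, plants one uninterrupted
#' run of the motif per protein (length drawn from the spec's run-length
#' distribution; flanking residues are redrawn from the non-motif alphabet so
#' the planted run cannot be extended by chance), assigns RRM annotations,
#' and labels proteins via the logistic model. When `dir` is given the
#' proteome is written in the dialects the ingestion functions consume:
#' a FASTA, an annotation TSV, three condensate list files (the union of
#' which is the label set) and a ground-truth TSV.
#'
#' @param spec [proteome_sim_spec()] object.
#' @param seed Integer seed (required; all randomness is local to the call).
#' @param dir Optional output directory.
#' @return data.frame with per-protein ground truth: `accession`,
#'   `sequence`, `planted_run`, `has_rrm`, `rrm_count`, `p_label`,
#'   `in_condensate`; when `dir` is given, file paths are attached as
#'   attribute `"paths"`.
#' @export
synth_proteome <- function(spec, seed, dir = NULL) {
  stopifnot(inherits(spec, "proteome_sim_spec"))
  if (missing(seed)) stop("an explicit seed is required")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- spec$n_proteins
  aa <- names(spec$background_freqs)
  m <- strsplit(spec$motif, "")[[1L]]
  non_motif <- setdiff(aa, m)
  nm_freq <- spec$background_freqs[non_motif]
  nm_freq <- nm_freq / sum(nm_freq)
  lens <- sample(names(spec$run_length_probs), n, replace = TRUE,
                 prob = spec$run_length_probs)
  lens <- as.integer(lens)
  seqs <- character(n)
  for (i in seq_len(n)) {
    l <- lens[i]
    repeat {                       # resample length until the run fits
      L <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
      if (L >= l + 2L) break
    }
    chars <- sample(aa, L, replace = TRUE, prob = spec$background_freqs)
    if (l > 0L) {
      pos <- sample(2L:(L - l), 1L)          # leave room for both flanks
      chars[pos:(pos + l - 1L)] <- strsplit(planted_run(spec$motif, l), "")[[1L]]
      chars[pos - 1L] <- sample(non_motif, 1L, prob = nm_freq)
      if (pos + l <= L)
        chars[pos + l] <- sample(non_motif, 1L, prob = nm_freq)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  has_rrm <- stats::runif(n) < spec$rrm_prevalence
  p <- stats::plogis(spec$beta0 + spec$beta1 * lens + spec$beta2 * has_rrm)
  labelled <- stats::runif(n) < p
  truth <- data.frame(
    accession = sprintf("SYN%05d", seq_len(n)),
    sequence = seqs, planted_run = lens,
    has_rrm = has_rrm, rrm_count = as.integer(has_rrm),
    p_label = p, in_condensate = labelled,
    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fasta <- file.path(dir, "proteome.fasta")
    set <- Biostrings::AAStringSet(truth$sequence)
    names(set) <- truth$accession
    Biostrings::writeXStringSet(set, fasta, width = 60L)
    ann <- file.path(dir, "annotations.tsv")
    utils::write.table(
      data.frame(accession = truth$accession, reviewed = TRUE,
                 protein_evidence = TRUE, rrm_count = truth$rrm_count),
      ann, sep = "\t", quote = FALSE, row.names = FALSE)
    # split the label set over three synthetic database exports whose union
    # is the full label set (each labelled protein lands in 1-3 of them)
    db_names <- c("synthetic_db1", "synthetic_db2", "synthetic_db3")
    lab_idx <- which(truth$in_condensate)
    membership <- lapply(db_names, function(d) character(0))
    names(membership) <- db_names
    if (length(lab_idx)) {
      primary <- sample(3L, length(lab_idx), replace = TRUE)
      for (k in 1:3) {
        extra <- stats::runif(length(lab_idx)) < 0.3
        sel <- primary == k | extra
        membership[[k]] <- truth$accession[lab_idx[sel]]
      }
    }
    cond_paths <- vapply(db_names, function(d) {
      p_ <- file.path(dir, paste0(d, ".txt"))
      writeLines(membership[[d]], p_)
      p_
    }, character(1))
    gt <- file.path(dir, "ground_truth.tsv")
    utils::write.table(truth, gt, sep = "\t", quote = FALSE, row.names = FALSE)
    attr(truth, "paths") <- list(fasta = fasta, annotations = ann,
                                 condensates = unname(cond_paths),
                                 ground_truth = gt)
  }
  truth
}

#' Specification of a synthetic PRE system
#'
#' Describes an ensemble of structures with one paramagnetic center and
#' per-residue amide protons whose center-proton distances are drawn
#' uniformly over a stated range, plus the acquisition parameters used to
#' simulate intensity decays. The default 8-20 Angstrom range spans the
#' informative window of a nitroxide label (close residues bleach, far ones
#' barely relax); the default time points (12 ms first observation delay,
#' 24 ms spacing) put `Gamma2 * dt` near 1 over that window.
#'
#' @param n_residues Number of observed residues (default 120).
#' @param distance_range Min/max center-proton distance in Angstrom
#'   (default `c(8, 20)`).
#' @param n_members Ensemble size N (default 10).
#' @param constants [pre_constants()] object (default 850 MHz, tau_c 4 ns).
#' @param times Acquisition time points in seconds
#'   (default `c(0.012, 0.036)`).
#' @param noise_sd Additive Gaussian intensity noise, as an absolute value on
#'   the `I0 = 1` scale (default 0.01, i.e. 1% of the initial intensity).
#' @param R2_dia Diamagnetic transverse relaxation rate (s^-1, default 10).
#' @param I0 Initial intensity (default 1).
#' @return Object of class `pre_sim_spec`.
#' @export
pre_sim_spec <- function(n_residues = 120L, distance_range = c(8, 20),
                         n_members = 10L,
                         constants = pre_constants(field_mhz = 850,
                                                   tau_c = 4e-9),
                         times = c(0.012, 0.036), noise_sd = 0.01,
                         R2_dia = 10, I0 = 1) {
  stopifnot(n_residues >= 1L, distance_range[1L] > 0,
            distance_range[2L] > distance_range[1L], n_members >= 1L,
            inherits(constants, "pre_constants"),
            length(times) >= 2L, all(diff(times) > 0),
            noise_sd >= 0, R2_dia > 0, I0 > 0)
  structure(list(n_residues = as.integer(n_residues),
                 distance_range = distance_range,
                 n_members = as.integer(n_members), constants = constants,
                 times = times, noise_sd = noise_sd, R2_dia = R2_dia,
                 I0 = I0),
            class = "pre_sim_spec")
}

# One fixed-width PDB coordinate line.
pdb_atom_line <- function(rec, serial, name, resn, chain, resno, xyz) {
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
          rec, serial, name, resn, chain, resno, xyz[1L], xyz[2L], xyz[3L],
          1, 0, substr(name, 1L, 1L))
}

#' Generate a synthetic PRE ensemble
#'
#' Draws a center-proton distance for every residue of every ensemble member,
#' realizes it as coordinates (paramagnetic center at the origin, proton on a
#' random direction), and computes the ground-truth ensemble-averaged Gamma2
#' with the forward model. Coordinates are quantized to the 0.001 Angstrom
#' precision of the PDB fixed format *before* the truth is computed, so a
#' written ensemble re-read from disk reproduces the truth to floating-point
#' accuracy.
#'
#' @param spec [pre_sim_spec()] object.
#' @param seed Integer seed (required).
#' @param path Optional output path for a multi-model PDB (the center is a
#'   `HETATM` named `O1` in residue `MTS`, the protons are `ATOM` records
#'   named `H`).
#' @return List with `dist` (members x residues matrix, Angstrom, after
#'   quantization), `truth` (data.frame `residue`, `gamma2_true`), and
#'   `path` (or `NULL`).
#' @export
synth_ensemble <- function(spec, seed, path = NULL) {
  stopifnot(inherits(spec, "pre_sim_spec"))
  if (missing(seed)) stop("an explicit seed is required")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- spec$n_residues; N <- spec$n_members
  r <- matrix(stats::runif(N * n, spec$distance_range[1L],
                           spec$distance_range[2L]), N, n)
  # random directions; quantize coordinates to PDB precision, then recompute
  # the distances actually encoded in the file
  u <- array(stats::rnorm(N * n * 3), dim = c(N, n, 3))
  coords <- array(0, dim = c(N, n, 3))
  for (i in seq_len(N)) for (j in seq_len(n)) {
    v <- u[i, j, ]
    coords[i, j, ] <- round(r[i, j] * v / sqrt(sum(v^2)), 3)
  }
  dist <- apply(coords, c(1, 2), function(v) sqrt(sum(v^2)))
  truth <- ensemble_gamma2(dist, spec$constants)
  truth <- data.frame(residue = truth$residue,
                      gamma2_true = truth$gamma2_calc)
  if (!is.null(path)) {
    lines <- character(0)
    for (i in seq_len(N)) {
      lines <- c(lines, sprintf("MODEL     %4d", i),
                 pdb_atom_line("HETATM", 1L, "O1", "MTS", "X", 999L,
                               c(0, 0, 0)))
      for (j in seq_len(n))
        lines <- c(lines, pdb_atom_line("ATOM", j + 1L, "H", "ALA", "A",
                                        j, coords[i, j, ]))
      lines <- c(lines, "ENDMDL")
    }
    writeLines(c(lines, "END"), path)
  }
  list(dist = dist, truth = truth, path = path)
}

#' Simulate a peak-intensity decay series
#'
#' Inverse of the two-point estimator: `I_dia(t) = I0 exp(-R2_dia t)` and
#' `I_para(t) = I_dia(t) exp(-gamma2 t)`, with additive Gaussian noise of
#' standard deviation `noise_sd` on every intensity. With `noise_sd = 0`
#' the two-point estimator recovers `gamma2_true` exactly.
#'
#' @param gamma2_true True Gamma2 (s^-1, scalar).
#' @param times Time points in seconds (strictly increasing).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @param R2_dia Diamagnetic relaxation rate (s^-1).
#' @param I0 Initial intensity.
#' @param residue Residue identifier carried through.
#' @return Decay series list (`residue`, `time_s`, `I_para`, `I_dia`,
#'   `noise_sd`) as consumed by [classify_residue()] and [fit_gamma2()].
#' @export
synth_decay <- function(gamma2_true, times = c(0.012, 0.036),
                        noise_sd = 0, seed = NULL, R2_dia = 10, I0 = 1,
                        residue = 1L) {
  stopifnot(length(times) >= 2L, all(diff(times) > 0), gamma2_true >= 0)
  I_dia <- I0 * exp(-R2_dia * times)
  I_para <- I_dia * exp(-gamma2_true * times)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("an explicit seed is required when noise_sd > 0")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    I_dia <- I_dia + stats::rnorm(length(times), 0, noise_sd)
    I_para <- I_para + stats::rnorm(length(times), 0, noise_sd)
  }
  list(residue = residue, time_s = times, I_para = I_para, I_dia = I_dia,
       noise_sd = noise_sd)
}

#' Simulate decay series for a whole residue set
#'
#' One decay series per residue of a ground-truth Gamma2 table, optionally
#' written as the CSV dialect read by [read_decay_series()]. For fixed seed
#' the written file is byte-identical across runs.
#'
#' @param truth data.frame with `residue` and `gamma2_true`.
#' @param spec [pre_sim_spec()] supplying times, noise, `R2_dia`, `I0`.
#' @param seed Integer seed (required).
#' @param path Optional CSV output path.
#' @return Named list of decay series.
#' @export
synth_decay_table <- function(truth, spec, seed, path = NULL) {
  stopifnot(inherits(spec, "pre_sim_spec"))
  if (missing(seed)) stop("an explicit seed is required")
  decays <- lapply(seq_len(nrow(truth)), function(i)
    synth_decay(truth$gamma2_true[i], times = spec$times,
                noise_sd = spec$noise_sd,
                seed = if (spec$noise_sd > 0) seed + i else NULL,
                R2_dia = spec$R2_dia, I0 = spec$I0,
                residue = truth$residue[i]))
  names(decays) <- as.character(truth$residue)
  if (!is.null(path)) {
    tab <- do.call(rbind, lapply(decays, function(s)
      data.frame(residue = s$residue, time_s = s$time_s,
                 I_para = sprintf("%.10g", s$I_para),
                 I_dia = sprintf("%.10g", s$I_dia),
                 sd = sprintf("%.10g", s$noise_sd))))
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  }
  decays
}
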