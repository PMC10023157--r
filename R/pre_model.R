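# Paramagnetic relaxation enhancement: Gamma2 forward model, ensemble
# averaging, Q-factor / Pearson validation, intensity-based Gamma2
# estimation and residue classification.

#' Physical constants for the PRE distance relationship
#'
#' Bundles the constants of the Solomon-Bloembergen Gamma2-distance relation
#' for a nitroxide spin label observed on amide protons:
#' `Gamma2 = r^-6 (mu0/4pi)^2 (1/15) gammaI^2 g^2 muB^2 S(S+1)
#'  (4 tau_c + 3 tau_c / (1 + (omegaH tau_c)^2))`.
#' The correlation time may be given directly or decomposed as
#' `1/tau_c = 1/tau_r + 1/tau_s` (rotational and electron-relaxation times).
#' All values are stored in SI; distances are converted from Angstrom at the
#' interface and Gamma2 is reported in s^-1.
#'
#' @param field_mhz Spectrometer proton frequency in MHz (default 850);
#'   `omega_H = 2 pi * field_mhz * 1e6`.
#' @param tau_c PRE correlation time in seconds. Required unless both
#'   `tau_r` and `tau_s` are given. There is no physically sensible default;
#'   supply the value appropriate to the system.
#' @param tau_r,tau_s Optional rotational / electron relaxation times (s).
#' @param S Electron spin quantum number (default 1/2, a nitroxide radical).
#' @param gamma_I Nuclear gyromagnetic ratio (rad s^-1 T^-1; default 1H).
#' @param g Electron g-factor.
#' @param mu_B Bohr magneton (J T^-1).
#' @param mu0 Vacuum permeability (T m A^-1).
#' @return Object of class `pre_constants`.
#' @export
pre_constants <- function(field_mhz = 850, tau_c = NULL,
                          tau_r = NULL, tau_s = NULL, S = 0.5,
                          gamma_I = 2.6752218744e8,
                          g = 2.00231930436,
                          mu_B = 9.2740100783e-24,
                          mu0 = 4 * pi * 1e-7) {
  if (is.null(tau_c)) {
    if (is.null(tau_r) || is.null(tau_s))
      stop("tau_c is required (or supply both tau_r and tau_s); ",
           "e.g. tau_c = 4e-9 for a ~4 ns effective correlation time")
    tau_c <- 1 / (1 / tau_r + 1 / tau_s)
  }
  stopifnot(field_mhz > 0, tau_c > 0, S > 0, gamma_I > 0, g > 0,
            mu_B > 0, mu0 > 0)
  structure(list(field_mhz = field_mhz, omega_H = 2 * pi * field_mhz * 1e6,
                 tau_c = tau_c, S = S, gamma_I = gamma_I, g = g,
                 mu_B = mu_B, mu0 = mu0),
            class = "pre_constants")
}

# Rate coefficient A such that Gamma2 = A * r^-6 with r in metres (A in
# m^6 s^-1): spectral-density and constant factors of the distance relation.
pre_rate_coefficient <- function(constants) {
  stopifnot(inherits(constants, "pre_constants"))
  with(constants,
       (mu0 / (4 * pi))^2 * (1 / 15) * gamma_I^2 * g^2 * mu_B^2 *
         S * (S + 1) *
         (4 * tau_c + 3 * tau_c / (1 + (omega_H * tau_c)^2)))
}

#' Gamma2 from a paramagnetic-center distance
#'
#' Evaluates the r^-6 PRE distance relation. Strictly decreasing in r:
#' doubling the distance divides Gamma2 by 64.
#'
#' @param r Distance(s) between the paramagnetic center (nitroxide oxygen)
#'   and the observed amide proton, in Angstrom; all > 0.
#' @param constants [pre_constants()] object.
#' @return Gamma2 in s^-1 (vectorized over `r`).
#' @export
gamma2_from_distance <- function(r, constants) {
  if (any(r <= 0)) stop("distances must be positive")
  pre_rate_coefficient(constants) / (r * 1e-10)^6
}

#' Read a structural ensemble for PRE back-calculation
#'
#' Parses a multi-model PDB (MODEL/ENDMDL records) and extracts, for every
#' ensemble member, the coordinates of the observed amide protons and of one
#' paramagnetic center (e.g. the nitroxide oxygen of an MTSL label).
#'
#' @param path Multi-model PDB file.
#' @param proton_atom Atom name of the observed nucleus (default `"H"`, the
#'   backbone amide proton).
#' @param center_atom Atom name of the paramagnetic center (default `"O1"`).
#' @param center_resname Optional residue-name filter for the center (e.g.
#'   `"MTS"`).
#' @param center_chain Optional chain filter for the center.
#' @return Object of class `pre_ensemble`: `residues` (resno vector),
#'   `n_models`, and `dist` (models x residues matrix of center-proton
#'   distances in Angstrom; `NA` where a residue lacks coordinates in a
#'   member).
#' @export
read_pre_ensemble <- function(path, proton_atom = "H", center_atom = "O1",
                              center_resname = NULL, center_chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  is_center <- at$elety == center_atom
  if (!is.null(center_resname)) is_center <- is_center & at$resid == center_resname
  if (!is.null(center_chain)) is_center <- is_center & at$chain == center_chain
  if (sum(is_center) != 1L)
    stop("expected exactly one paramagnetic-center atom per model, found ",
         sum(is_center))
  is_h <- at$elety == proton_atom & !is_center
  if (!any(is_h)) stop("no atoms named ", proton_atom, " found")
  residues <- at$resno[is_h]
  if (anyDuplicated(residues))
    stop("multiple ", proton_atom, " atoms share a residue number")
  xyz <- pdb$xyz                       # models x (3 * natoms)
  n_models <- nrow(xyz)
  cidx <- which(is_center); hidx <- which(is_h)
  coord <- function(model, atom_idx)
    xyz[model, c(3 * atom_idx - 2, 3 * atom_idx - 1, 3 * atom_idx)]
  dist <- matrix(NA_real_, n_models, length(hidx))
  for (m in seq_len(n_models)) {
    ctr <- coord(m, cidx)
    for (j in seq_along(hidx)) {
      hc <- coord(m, hidx[j])
      if (!anyNA(hc) && !anyNA(ctr))
        dist[m, j] <- sqrt(sum((hc - ctr)^2))
    }
  }
  structure(list(residues = residues, n_models = n_models, dist = dist),
            class = "pre_ensemble")
}

#' Ensemble-averaged back-calculated Gamma2
#'
#' For each residue h the effective interaction is the ensemble average
#' `<r^-6>_h = (1/N) sum_i r_i^-6` over the N members, so
#' `Gamma2_calc(h) = A * <r^-6>_h`. With a single member (or identical
#' members) this reduces to [gamma2_from_distance()] at that geometry.
#' Residues lacking coordinates in one or more members are back-calculated
#' over the members that have them and flagged; residues with no usable
#' member give `NA`.
#'
#' @param ensemble `pre_ensemble` object from [read_pre_ensemble()], or a
#'   numeric matrix of distances (models x residues, Angstrom).
#' @param constants [pre_constants()] object.
#' @return data.frame with `residue`, `gamma2_calc` (s^-1) and
#'   `n_members_used`.
#' @export
ensemble_gamma2 <- function(ensemble, constants) {
  if (inherits(ensemble, "pre_ensemble")) {
    dist <- ensemble$dist; residues <- ensemble$residues
  } else {
    dist <- as.matrix(ensemble)
    residues <- seq_len(ncol(dist))
  }
  if (any(dist <= 0, na.rm = TRUE)) stop("distances must be positive")
  A <- pre_rate_coefficient(constants)
  inv6 <- (dist * 1e-10)^(-6)
  mean_inv6 <- colMeans(inv6, na.rm = TRUE)
  n_used <- colSums(!is.na(inv6))
  mean_inv6[n_used == 0L] <- NA_real_
  data.frame(residue = residues, gamma2_calc = A * mean_inv6,
             n_members_used = n_used, row.names = NULL)
}

#' Q-factor of observed versus back-calculated PRE
#'
#' `Q = sqrt( sum_h (obs_h - calc_h)^2 / sum_h obs_h^2 )` over the residues
#' with defined values. Q = 0 means perfect agreement; a calculated profile
#' scaled by c against the observed one gives Q = |1 - c|.
#'
#' @param gamma2_obs,gamma2_calc Equal-length numeric vectors (s^-1), flags
#'   already applied.
#' @return Q (non-negative scalar).
#' @export
q_factor <- function(gamma2_obs, gamma2_calc) {
  stopifnot(length(gamma2_obs) == length(gamma2_calc),
            length(gamma2_obs) > 0)
  keep <- !is.na(gamma2_obs) & !is.na(gamma2_calc)
  obs <- gamma2_obs[keep]; calc <- gamma2_calc[keep]
  if (length(obs) == 0) stop("no residues with defined observed and calculated values")
  if (all(obs == 0)) stop("observed Gamma2 vector is all zero")
  sqrt(sum((obs - calc)^2) / sum(obs^2))
}

#' Pearson correlation of observed versus back-calculated PRE
#'
#' Standard product-moment correlation over residues with defined values.
#'
#' @inheritParams q_factor
#' @return R in `[-1, 1]`, or `NA` (with a warning) when either vector has
#'   zero variance or fewer than 3 residues remain.
#' @export
pearson_pre <- function(gamma2_obs, gamma2_calc) {
  stopifnot(length(gamma2_obs) == length(gamma2_calc))
  keep <- !is.na(gamma2_obs) & !is.na(gamma2_calc)
  obs <- gamma2_obs[keep]; calc <- gamma2_calc[keep]
  if (length(obs) < 3) {
    warning("fewer than 3 residues with defined values; R undefined")
    return(NA_real_)
  }
  if (stats::sd(obs) == 0 || stats::sd(calc) == 0) {
    warning("zero variance; R undefined")
    return(NA_real_)
  }
  stats::cor(obs, calc)
}

#' Classify a residue's peak-intensity decay series
#'
#' A residue is *noisy* when its diamagnetic intensity at the second time
#' point is below five times the spectrum noise standard deviation (strict
#' `<`), and *bleached* when the paramagnetic/diamagnetic intensity ratio at
#' the first time point is at most one half (inclusive `<=`; relaxation too
#' fast to fit). A residue meeting both definitions is excluded outright.
#'
#' @param series Decay series: a list or one-residue data.frame with fields
#'   `time_s` (strictly increasing, >= 2 points), `I_para`, `I_dia`, and
#'   `noise_sd` (per-spectrum scalar).
#' @return One of `"ok"`, `"bleached"`, `"noisy"`, `"excluded"`.
#' @export
classify_residue <- function(series) {
  s <- validate_series(series)
  noisy <- s$I_dia[2L] < 5 * s$noise_sd
  bleached <- s$I_para[1L] / s$I_dia[1L] <= 0.5
  if (noisy && bleached) "excluded"
  else if (bleached) "bleached"
  else if (noisy) "noisy"
  else "ok"
}

validate_series <- function(series) {
  s <- as.list(series)
  need <- c("time_s", "I_para", "I_dia", "noise_sd")
  if (!all(need %in% names(s)))
    stop("decay series needs fields: ", paste(need, collapse = ", "))
  t <- s$time_s
  if (length(t) < 2L || any(diff(t) <= 0))
    stop("decay series needs >= 2 strictly increasing time points")
  stopifnot(length(s$I_para) == length(t), length(s$I_dia) == length(t))
  s$noise_sd <- s$noise_sd[1L]
  s
}

#' Estimate Gamma2 from a peak-intensity decay series
#'
#' Default two-time-point estimator:
#' `Gamma2 = ln( I_dia(t2) I_para(t1) / (I_dia(t1) I_para(t2)) ) / (t2 - t1)`
#' with the uncertainty propagated to first order from the per-spectrum noise
#' standard deviation (each of the four intensities contributes
#' `(sd / I)^2` to the variance of the log ratio). A multi-point weighted
#' least-squares fit of `ln(I_para / I_dia)` against time is selectable for
#' series with more than two usable points.
#'
#' @param series Decay series, see [classify_residue()].
#' @param method `"two_point"` (default) or `"lsq"`.
#' @return Named list with `gamma2` (s^-1) and `uncertainty` (s^-1, 1 sd).
#' @export
fit_gamma2 <- function(series, method = c("two_point", "lsq")) {
  method <- match.arg(method)
  s <- validate_series(series)
  if (method == "two_point") {
    i <- c(1L, 2L)
    I <- c(s$I_dia[i], s$I_para[i])
    if (any(I <= 0)) stop("nonpositive intensity at a used time point")
    dt <- s$time_s[2L] - s$time_s[1L]
    g2 <- log((s$I_dia[2L] * s$I_para[1L]) / (s$I_dia[1L] * s$I_para[2L])) / dt
    unc <- s$noise_sd * sqrt(sum(1 / I^2)) / dt
    list(gamma2 = g2, uncertainty = unc)
  } else {
    if (any(s$I_para <= 0) || any(s$I_dia <= 0))
      stop("nonpositive intensity at a used time point")
    y <- log(s$I_para / s$I_dia)
    vy <- s$noise_sd^2 * (1 / s$I_para^2 + 1 / s$I_dia^2)
    w <- if (all(vy == 0)) rep(1, length(y)) else 1 / vy
    fit <- stats::lm(y ~ s$time_s, weights = w)
    slope <- unname(stats::coef(fit)[2L])
    # first-order propagated slope variance under the known per-point noise
    tbar <- sum(w * s$time_s) / sum(w)
    sxx <- sum(w * (s$time_s - tbar)^2)
    unc <- if (all(vy == 0)) 0 else sqrt(1 / sxx)
    list(gamma2 = -slope, uncertainty = unc)
  }
}

#' Read peak-intensity decay series from CSV
#'
#' Expected columns: `residue`, `time_s`, `I_para`, `I_dia`, `sd` (the
#' per-spectrum noise standard deviation, repeated on each row of a
#' spectrum's time point).
#'
#' @param path CSV file.
#' @return Named list of decay series (one per residue), each a list with
#'   `residue`, `time_s`, `I_para`, `I_dia`, `noise_sd`.
#' @export
read_decay_series <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue", "time_s", "I_para", "I_dia", "sd")
  if (!all(need %in% names(tab)))
    stop("decay CSV needs columns: ", paste(need, collapse = ", "))
  lapply(split(tab, tab$residue), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    list(residue = d$residue[1L], time_s = d$time_s,
         I_para = d$I_para, I_dia = d$I_dia, noise_sd = d$sd[1L])
  })
}

#' Reduce decay series to an observed PRE profile
#'
#' Classifies every residue and fits Gamma2 for those classified `"ok"`.
#'
#' @param decays List of decay series from [read_decay_series()] (or built
#'   in code).
#' @param method Estimator passed to [fit_gamma2()].
#' @return data.frame: `residue`, `gamma2_obs`, `gamma2_err`, `flag`.
#' @export
fit_decay_table <- function(decays, method = c("two_point", "lsq")) {
  method <- match.arg(method)
  rows <- lapply(decays, function(s) {
    flag <- classify_residue(s)
    if (flag == "ok") {
      f <- fit_gamma2(s, method)
      data.frame(residue = s$residue, gamma2_obs = f$gamma2,
                 gamma2_err = f$uncertainty, flag = flag)
    } else {
      data.frame(residue = s$residue, gamma2_obs = NA_real_,
                 gamma2_err = NA_real_, flag = flag)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$residue), , drop = FALSE]
}

#' Validate observed against back-calculated PRE
#'
#' Joins an observed profile with a back-calculated one on residue number,
#' drops residues flagged bleached/noisy/excluded and residues with
#' undefined values, and reports the Q-factor, Pearson R and the number of
#' residues used.
#'
#' @param obs data.frame from [fit_decay_table()] (columns `residue`,
#'   `gamma2_obs`, optional `flag`).
#' @param calc data.frame from [ensemble_gamma2()] (columns `residue`,
#'   `gamma2_calc`).
#' @return Named list: `Q`, `R`, `n`.
#' @export
pre_validate <- function(obs, calc) {
  merged <- merge(obs, calc, by = "residue")
  if ("flag" %in% names(merged))
    merged <- merged[merged$flag == "ok", , drop = FALSE]
  merged <- merged[!is.na(merged$gamma2_obs) & !is.na(merged$gamma2_calc), ,
                   drop = FALSE]
  if (nrow(merged) == 0L) stop("no usable residues")
  list(Q = q_factor(merged$gamma2_obs, merged$gamma2_calc),
       R = pearson_pre(merged$gamma2_obs, merged$gamma2_calc),
       n = nrow(merged))
}

#' Distance at which bleaching is expected
#'
#' Inverts the forward model to the distance at which the paramagnetic /
#' diamagnetic intensity ratio at the first observation delay equals a
#' threshold: solves `exp(-Gamma2(r) * t1) = ratio_threshold`. Larger tau_c
#' (stronger PRE) pushes this distance outward; doubling `t1` at fixed
#' threshold scales it by `2^(1/6)`.
#'
#' @param constants [pre_constants()] object.
#' @param ratio_threshold Intensity ratio in (0, 1) (default 0.5, the
#'   bleached definition).
#' @param t1 First observation delay in seconds (default 0.012).
#' @return Distance in Angstrom.
#' @export
bleach_distance <- function(constants, ratio_threshold = 0.5, t1 = 0.012) {
  stopifnot(ratio_threshold > 0, ratio_threshold < 1, t1 > 0)
  g2_star <- -log(ratio_threshold) / t1
  (pre_rate_coefficient(constants) / g2_star)^(1 / 6) * 1e10
}
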