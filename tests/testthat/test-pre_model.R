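cst <- pre_constants(field_mhz = 850, tau_c = 4e-9)

test_that("forward model: r^-6 law, monotonicity, constants plumbing", {
  expect_equal(gamma2_from_distance(30, cst) / gamma2_from_distance(15, cst),
               1 / 64)
  r <- seq(5, 60, by = 0.5)
  g <- gamma2_from_distance(r, cst)
  expect_true(all(diff(g) < 0))
  expect_lt(gamma2_from_distance(1e4, cst), 1e-10)
  expect_error(gamma2_from_distance(c(10, -1), cst), "positive")

  # high-precision direct evaluation of the distance relation at r = 15 A
  direct <- with(unclass(cst), {
    (1e-7)^2 / 15 * gamma_I^2 * g^2 * mu_B^2 * S * (S + 1) *
      (4 * tau_c + 3 * tau_c / (1 + (omega_H * tau_c)^2)) / (15e-10)^6
  })
  expect_equal(gamma2_from_distance(15, cst), direct, tolerance = 1e-12)

  # tau_c decomposition: 1/tau_c = 1/tau_r + 1/tau_s
  c2 <- pre_constants(850, tau_r = 8e-9, tau_s = 8e-9)
  expect_equal(c2$tau_c, 4e-9)
  expect_error(pre_constants(850), "tau_c")
})

test_that("ensemble averaging: degenerate, two-member and random cases", {
  # degenerate ensemble equals the single-distance forward value
  d <- matrix(12, nrow = 5, ncol = 3)
  eg <- ensemble_gamma2(d, cst)
  expect_equal(eg$gamma2_calc, rep(gamma2_from_distance(12, cst), 3))

  # two members at r and 2r: proportional to (r^-6 + (2r)^-6) / 2
  two <- ensemble_gamma2(matrix(c(10, 20), nrow = 2, ncol = 1), cst)
  expect_equal(two$gamma2_calc,
               (gamma2_from_distance(10, cst) +
                  gamma2_from_distance(20, cst)) / 2)

  # random ensemble matches the brute-force per-member average
  set.seed(43)
  dm <- matrix(stats::runif(10 * 8, 8, 30), 10, 8)
  got <- ensemble_gamma2(dm, cst)$gamma2_calc
  brute <- apply(dm, 2, function(col)
    mean(vapply(col, gamma2_from_distance, numeric(1), constants = cst)))
  expect_equal(got, brute)

  # ensemble value lies between the member extremes
  per_member <- apply(dm, c(1, 2), gamma2_from_distance, constants = cst)
  expect_true(all(got >= apply(per_member, 2, min) - 1e-12))
  expect_true(all(got <= apply(per_member, 2, max) + 1e-12))
})

test_that("Q-factor and Pearson R identities and oracle agreement", {
  set.seed(47)
  obs <- stats::runif(20, 1, 60)
  expect_equal(q_factor(obs, obs), 0)
  expect_equal(q_factor(obs, 2 * obs), 1)
  expect_equal(q_factor(obs, rep(0, 20)), 1)
  for (c_ in c(0.3, 0.9, 1.7, 2.5))
    expect_equal(q_factor(obs, c_ * obs), abs(1 - c_))
  perm <- sample(20)   # Q is invariant to residue reordering
  expect_equal(q_factor(obs[perm], (2 * obs)[perm]), 1)
  expect_error(q_factor(rep(0, 5), rep(1, 5)), "all zero")

  expect_equal(pearson_pre(obs, 3 * obs + 2), 1)
  expect_equal(pearson_pre(obs, -obs), -1)
  calc <- stats::runif(20, 1, 60)
  direct <- sum((obs - mean(obs)) * (calc - mean(calc))) /
    sqrt(sum((obs - mean(obs))^2) * sum((calc - mean(calc))^2))
  expect_equal(pearson_pre(obs, calc), direct, tolerance = 1e-12)
  expect_warning(r0 <- pearson_pre(rep(2, 5), 1:5), "zero variance")
  expect_true(is.na(r0))
})

test_that("residue classification: boundary conventions as stated", {
  mk <- function(ratio1, dia2_over_sd) {
    I0 <- 100
    list(time_s = c(0.012, 0.036),
         I_para = c(ratio1 * I0, ratio1 * I0 * 0.8),
         I_dia = c(I0, dia2_over_sd * 1),
         noise_sd = 1)
  }
  expect_equal(classify_residue(mk(0.5, 100)), "bleached")   # <= included
  expect_equal(classify_residue(mk(0.501, 100)), "ok")
  expect_equal(classify_residue(mk(0.9, 4.9)), "noisy")      # strict <
  expect_equal(classify_residue(mk(0.9, 5.0)), "ok")
  expect_equal(classify_residue(mk(0.4, 4.9)), "excluded")   # both
})

test_that("Gamma2 fitting: exact inversion, propagation, failure modes", {
  s <- synth_decay(30, noise_sd = 0)
  expect_equal(fit_gamma2(s)$gamma2, 30)
  s0 <- synth_decay(0, noise_sd = 0)
  expect_equal(fit_gamma2(s0)$gamma2, 0)

  bad <- list(time_s = c(0.012, 0.036), I_para = c(1, -0.1),
              I_dia = c(1, 0.5), noise_sd = 0.01)
  expect_error(fit_gamma2(bad), "nonpositive")

  # Monte-Carlo: mean recovery and uncertainty calibration at 1% noise
  fits <- vapply(1:200, function(i) {
    f <- fit_gamma2(synth_decay(30, noise_sd = 0.01, seed = i))
    c(f$gamma2, f$uncertainty)
  }, numeric(2))
  expect_lt(abs(mean(fits[1, ]) - 30) / 30, 0.02)
  expect_lt(abs(stats::sd(fits[1, ]) - mean(fits[2, ])) / mean(fits[2, ]), 0.5)

  # multi-point least squares agrees with the generator too
  s4 <- synth_decay(25, times = c(0.012, 0.02, 0.03, 0.04), noise_sd = 0)
  expect_equal(fit_gamma2(s4, method = "lsq")$gamma2, 25)
})

test_that("bleach distance inversion behaves physically", {
  d <- bleach_distance(cst, 0.5, 0.012)
  expect_gt(d, 10); expect_lt(d, 16)   # low-to-mid tens of Angstrom
  expect_equal(bleach_distance(cst, 0.5, 0.024) / d, 2^(1 / 6),
               tolerance = 1e-12)
  expect_gt(bleach_distance(cst, 0.999, 0.012), d)   # threshold -> 1 grows
  # stronger PRE (larger tau_c) pushes the bleach radius outward
  expect_gt(bleach_distance(pre_constants(850, tau_c = 8e-9)), d)
  # forward/backward consistency
  expect_equal(exp(-gamma2_from_distance(d, cst) * 0.012), 0.5,
               tolerance = 1e-10)
})

test_that("PDB ensemble round trip reproduces the generated truth", {
  spec <- pre_sim_spec(n_residues = 15, n_members = 4)
  path <- tempfile(fileext = ".pdb")
  ens <- synth_ensemble(spec, seed = 53, path = path)
  re <- read_pre_ensemble(path)
  expect_equal(re$n_models, 4L)
  expect_equal(re$residues, 1:15)
  back <- ensemble_gamma2(re, spec$constants)
  expect_equal(back$gamma2_calc, ens$truth$gamma2_true, tolerance = 1e-9)
})

test_that("validation joins profiles, applies flags, reports Q/R/n", {
  obs <- data.frame(residue = 1:6,
                    gamma2_obs = c(10, 20, NA, 40, 50, 60),
                    flag = c("ok", "ok", "bleached", "ok", "noisy", "ok"))
  calc <- data.frame(residue = 1:6, gamma2_calc = c(10, 20, 30, 40, 50, 60))
  v <- pre_validate(obs, calc)
  expect_equal(v$n, 4L)    # residues 1, 2, 4, 6
  expect_equal(v$Q, 0)
  expect_equal(v$R, 1)
  all_bleached <- transform(obs, flag = "bleached")
  expect_error(pre_validate(all_bleached, calc), "no usable residues")
})
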