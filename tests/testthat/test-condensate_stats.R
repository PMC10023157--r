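test_that("category tables: nesting, exclusion of x = 0, direct counts", {
  tab <- toy_protein_table()
  scans <- scan_proteins(tab)
  L <- longest_runs_for_motif(scans, tab$accession, "RS")
  expect_equal(L, c(16L, 4L, 2L, 0L, 0L, 5L))
  ct <- categorize(L, tab$in_condensate)

  # direct-count oracle over the toy table
  expect_equal(ct$N_ps, c(sum(tab$in_condensate[L < 2]),
                          sum(tab$in_condensate[L >= 2]),
                          sum(tab$in_condensate[L >= 4]),
                          sum(tab$in_condensate[L >= 6]),
                          sum(tab$in_condensate[L >= 8])))
  # a 16-mer protein is in every cumulative category, not in x = 0
  expect_true(all((ct$N_ps + ct$N_np)[2:5] >= 1))
  sizes <- ct$N_ps + ct$N_np
  expect_true(all(diff(sizes[2:5]) <= 0))          # nesting
  expect_equal(sizes[1] + sizes[2], length(L))     # x=0 disjoint from x>=2

  # 10 proteins, 3 with runs >= 4, 2 of those labelled
  L2 <- c(16L, 6L, 4L, rep(0L, 7))
  lab <- c(TRUE, TRUE, FALSE, rep(FALSE, 7))
  ct2 <- categorize(L2, lab)
  expect_equal(ct2$N_ps[ct2$x == 4], 2L)
  expect_equal(ct2$N_np[ct2$x == 4], 1L)
  expect_equal(ct2$f_ps[ct2$x == 4], 2 / 3)
})

test_that("nesting invariant holds on random category tables", {
  set.seed(19)
  for (i in 1:30) {
    n <- sample(20:200, 1)
    L <- sample(c(0L, 1L, 2L, 3L, 4L, 6L, 8L, 12L, 16L), n, replace = TRUE)
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    ct <- categorize(L, lab)
    sizes <- ct$N_ps + ct$N_np
    expect_true(all(diff(sizes[2:5]) <= 0))
    expect_true(all(diff(ct$N_ps[2:5]) <= 0))
    expect_equal(sizes[1] + sizes[2], n)
    ok <- !is.na(ct$f_ps)
    expect_true(all(ct$f_ps[ok] >= 0 & ct$f_ps[ok] <= 1))
  }
})

test_that("fraction and population error forms", {
  fe <- fraction_and_error(9, 27)
  expect_equal(fe$f_ps, 0.25)
  expect_equal(fraction_and_error(25, 10)$E_ps, 0.2)
  expect_equal(fraction_and_error(25, 10, eps_form = "linear")$E_ps, 0.04)
  z <- fraction_and_error(0, 5)
  expect_equal(z$f_ps, 0)
  expect_true(is.na(z$E_ps))
})

test_that("correlation screen: t-transform p, criteria, degeneracies", {
  make_ct <- function(f, N_ps = c(10, 40, 30, 20, 12)) {
    data.frame(x = c(0, 2, 4, 6, 8), cumulative = c(FALSE, rep(TRUE, 4)),
               N_ps = N_ps, N_np = round(N_ps * (1 - f) / pmax(f, 1e-9)),
               f_ps = f, E_ps = 1 / sqrt(N_ps))
  }
  scr <- correlation_screen(make_ct(c(0.1, 0.2, 0.35, 0.5, 0.7)))
  # independent check against R's own correlation test
  ref <- stats::cor.test(c(0, 2, 4, 6, 8), c(0.1, 0.2, 0.35, 0.5, 0.7))
  expect_equal(scr$pearson_r, unname(ref$estimate))
  expect_equal(scr$p_two_tailed, ref$p.value)
  expect_true(scr$significant)

  # flat fractions: zero variance, not significant
  flat <- correlation_screen(make_ct(rep(0.3, 5)))
  expect_true(is.na(flat$pearson_r))
  expect_false(flat$significant)

  # monotone decreasing p in |r| at fixed n
  rs <- seq(0.5, 0.99, by = 0.07)
  ps <- vapply(rs, function(r) {
    t <- r * sqrt(3) / sqrt(1 - r^2)
    2 * stats::pt(-abs(t), 3)
  }, numeric(1))
  expect_true(all(diff(ps) < 0))

  # fewer than 3 defined categories -> undefined, not significant
  ct <- make_ct(c(0.1, 0.2, 0.3, 0.4, 0.5))
  ct$f_ps[3:5] <- NA
  few <- correlation_screen(ct)
  expect_true(is.na(few$p_two_tailed))
  expect_false(few$significant)

  # error criterion: empty x >= 8 category fails it even with strong r
  ct8 <- make_ct(c(0.1, 0.2, 0.35, 0.5, 0.7))
  ct8$N_ps[5] <- 0L; ct8$E_ps[5] <- NA
  expect_false(correlation_screen(ct8)$passes_error_criterion)
})

test_that("Fisher's exact test matches exhaustive enumeration", {
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 5), 2)), 1)  # zero column
  t1 <- matrix(c(2, 7, 8, 3), 2)
  expect_equal(fisher_exact(t1), fisher_enum_oracle(t1))
  expect_equal(fisher_exact(t1), fisher_exact(t(t1)))      # symmetry
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  set.seed(29)
  for (i in 1:200) {
    total <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, total, prob = stats::runif(4, 0.05, 1)))
    tab <- matrix(cells, 2)
    expect_equal(fisher_exact(tab), fisher_enum_oracle(tab), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney: orientation, ties, exact-variance oracle", {
  allties <- mann_whitney(rep(1, 4), rep(1, 6))
  expect_equal(allties$U, 4 * 6 / 2)
  expect_equal(allties$p_two_tailed, 1)

  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)   # U oriented to the first sample

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")

  set.seed(31)
  for (i in 1:40) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    a <- sample(1:6, na, replace = TRUE)   # heavy ties
    b <- sample(1:6, nb, replace = TRUE)
    got <- mann_whitney(a, b)
    want <- mw_perm_oracle(a, b)
    expect_equal(got$U, want$U)
    if (want$p < 1)
      expect_equal(got$p_two_tailed, want$p, tolerance = 1e-12)
  }
})

test_that("Bonferroni adjustment", {
  expect_equal(bonferroni(0.05, 2), 0.025)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.05, 5), 0.01)
  expect_error(bonferroni(1.2, 2))
})

test_that("size-matched resampling is seeded, reproducible and guarded", {
  set.seed(37)
  n <- 400
  L <- sample(c(0L, 2L, 4L, 6L, 8L, 10L, 16L), n, replace = TRUE,
              prob = c(0.3, 0.2, 0.15, 0.12, 0.1, 0.08, 0.05))
  lab <- stats::runif(n) < stats::plogis(-1 + 0.2 * L)
  r1 <- size_matched_resample(L, lab, n_subsets = 10, seed = 99)
  r2 <- size_matched_resample(L, lab, n_subsets = 10, seed = 99)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 10L)
  sizes <- c(sum(L < 2), sum(L >= 2), sum(L >= 4), sum(L >= 6), sum(L >= 8))
  expect_true(all(r1$matched_n == min(sizes)))
  expect_error(size_matched_resample(c(0L, 0L, 16L), c(TRUE, FALSE, TRUE),
                                     n_subsets = 5, seed = 1),
               "fewer than 3")
  expect_error(size_matched_resample(L, lab, n_subsets = 5), "seed")
})

test_that("motif screen recovers planted enrichment and respects nulls", {
  spec <- proteome_sim_spec(n_proteins = 600L)
  truth <- synth_proteome(spec, seed = 404)
  scans <- scan_proteins(truth[, c("accession", "sequence")])
  assoc <- motif_association_screen(
    scans, data.frame(accession = truth$accession,
                      in_condensate = truth$in_condensate))
  expect_true("RS" %in% assoc$motif[assoc$significant])
  rs <- assoc[assoc$motif == "RS", ]
  expect_true(rs$pearson_r > 0 && rs$p_two_tailed < 0.05)
})
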