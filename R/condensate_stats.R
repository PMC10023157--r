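# Repeat-length category tables, population-based errors, correlation
# screening, contingency and rank statistics, and size-matched resampling.

CATEGORY_X <- c(0L, 2L, 4L, 6L, 8L)

#' Condensate fraction and population-based error
#'
#' For a repeat-length category holding `N_ps` proteins found in condensates
#' and `N_np` proteins not found in condensates, the condensate fraction is
#' `f_ps = N_ps / (N_ps + N_np)`. The population-based error is
#' `E_ps = 1 / sqrt(N_ps)` by default (counting statistics on the condensate
#' count); the linear form `1 / N_ps` is selectable. `E_ps` is undefined
#' (`NA`) when `N_ps = 0`, and `f_ps` is undefined when the category is
#' empty.
#'
#' @param N_ps,N_np Non-negative integer counts.
#' @param eps_form `"sqrt"` (default) or `"linear"`.
#' @return Named list with `f_ps` and `E_ps`.
#' @export
fraction_and_error <- function(N_ps, N_np, eps_form = c("sqrt", "linear")) {
  eps_form <- match.arg(eps_form)
  stopifnot(N_ps >= 0, N_np >= 0)
  f <- if (N_ps + N_np > 0) N_ps / (N_ps + N_np) else NA_real_
  e <- if (N_ps > 0) {
    if (eps_form == "sqrt") 1 / sqrt(N_ps) else 1 / N_ps
  } else NA_real_
  list(f_ps = f, E_ps = e)
}

#' Repeat-length category table for one motif
#'
#' Proteins are placed in five categories by the length x of their longest
#' uninterrupted run of the motif: x = 0 (no run of length >= 2 anywhere in
#' the sequence), and the cumulative categories x >= 2, x >= 4, x >= 6,
#' x >= 8. A protein with a 16-mer run belongs to all four cumulative
#' categories; only the x = 0 category is disjoint from the rest. Only the
#' longest run counts; the number of runs plays no role here.
#'
#' @param longest_runs Integer vector: per-protein longest run of the motif
#'   (0 when absent).
#' @param in_condensate Logical vector of condensate labels, same length.
#' @param eps_form Error form, see [fraction_and_error()].
#' @return data.frame with one row per category: `x` (0, 2, 4, 6, 8),
#'   `cumulative` (FALSE for x = 0), `N_ps`, `N_np`, `f_ps`, `E_ps`.
#' @export
categorize <- function(longest_runs, in_condensate,
                       eps_form = c("sqrt", "linear")) {
  eps_form <- match.arg(eps_form)
  stopifnot(length(longest_runs) == length(in_condensate),
            is.logical(in_condensate))
  keep <- !is.na(longest_runs) & !is.na(in_condensate)
  if (sum(!keep) > 0)
    message(sum(!keep), " protein(s) with undefined category excluded")
  L <- longest_runs[keep]
  ps <- in_condensate[keep]
  rows <- lapply(CATEGORY_X, function(x) {
    in_cat <- if (x == 0L) L < 2L else L >= x
    fe <- fraction_and_error(sum(in_cat & ps), sum(in_cat & !ps), eps_form)
    data.frame(x = x, cumulative = x > 0L,
               N_ps = sum(in_cat & ps), N_np = sum(in_cat & !ps),
               f_ps = fe$f_ps, E_ps = fe$E_ps)
  })
  do.call(rbind, rows)
}

#' Correlation screen of repeat length against condensate fraction
#'
#' Pearson correlation of the five category abscissae x = 0, 2, 4, 6, 8
#' against the category condensate fractions `f_ps`, with the two-tailed
#' p-value from the t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on
#' n - 2 degrees of freedom. A motif passes the population-error criterion
#' when its x >= 8 category is populated (`N_ps > 0`, so `E_ps` is defined)
#' and `E_ps(x >= 8) < 2 * f_ps(x >= 8)`. The motif is flagged significant
#' when r > 0, p < alpha and the error criterion passes.
#'
#' @param category_table data.frame from [categorize()].
#' @param alpha Two-tailed significance level (default 0.05).
#' @return One-row data.frame: `n_categories` (with defined `f_ps`),
#'   `pearson_r`, `p_two_tailed`, `passes_error_criterion`, `significant`.
#' @export
correlation_screen <- function(category_table, alpha = 0.05) {
  stopifnot(all(c("x", "f_ps", "E_ps", "N_ps") %in% names(category_table)))
  ok <- !is.na(category_table$f_ps)
  n <- sum(ok)
  x <- category_table$x[ok]
  f <- category_table$f_ps[ok]
  r <- NA_real_; p <- NA_real_
  if (n >= 3 && stats::sd(x) > 0 && stats::sd(f) > 0) {
    r <- stats::cor(x, f)
    if (abs(r) < 1) {
      tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    } else p <- 0
  }
  i8 <- which(category_table$x == 8L)
  e8 <- category_table$E_ps[i8]
  f8 <- category_table$f_ps[i8]
  passes <- length(i8) == 1L && !is.na(e8) && !is.na(f8) && e8 < 2 * f8
  sig <- !is.na(r) && !is.na(p) && r > 0 && p < alpha && passes
  data.frame(n_categories = n, pearson_r = r, p_two_tailed = p,
             passes_error_criterion = passes, significant = sig)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided p-value by the probability-mass rule: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table. Degenerate margins (a zero
#' row or column) give p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0)) stop("contingency table cells must be non-negative")
  if (any(table != round(table))) stop("contingency table cells must be integers")
  if (sum(table) == 0 || any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(1)
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples with midrank ties. The U statistic is
#' oriented to the first sample: `U = #{pairs with a > b} + 0.5 * #{ties}`,
#' so complete separation with all of `a` below `b` gives U = 0. The
#' two-sided p-value uses the normal approximation with the tie-corrected
#' variance (identical to the exact permutation variance of U under ties),
#' without continuity correction unless requested.
#'
#' @param a,b Numeric samples (sizes may differ; both non-empty).
#' @param continuity Apply the 0.5 continuity correction (default `FALSE`).
#' @return Named list with `U` and `p_two_tailed`.
#' @export
mann_whitney <- function(a, b, continuity = FALSE) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = FALSE, correct = continuity))
  U <- unname(wt$statistic)
  p <- wt$p.value
  if (is.nan(p)) p <- 1   # zero variance: samples are one big tie group
  list(U = U, p_two_tailed = p)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Per-motif association screen over a scanned proteome
#'
#' Builds the category table and correlation screen for each motif. Motifs
#' not present in `scans` have every protein in x = 0 and are skipped unless
#' explicitly requested.
#'
#' @param scans Long-format scan table from [scan_proteins()].
#' @param proteins Protein table with `accession` and `in_condensate`.
#' @param motifs `"all"` (every motif appearing in `scans`) or a character
#'   vector.
#' @param eps_form Error form, see [fraction_and_error()].
#' @param alpha Significance level for the correlation screen.
#' @return data.frame with one row per motif: the screen columns of
#'   [correlation_screen()] plus per-category counts `N_ps_0` ... `f_ps_8`.
#' @export
motif_association_screen <- function(scans, proteins, motifs = "all",
                                     eps_form = c("sqrt", "linear"),
                                     alpha = 0.05) {
  eps_form <- match.arg(eps_form)
  if (identical(motifs, "all")) motifs <- sort(unique(scans$motif))
  else motifs <- vapply(motifs, normalize_motif, character(1))
  by_motif <- split(scans[, c("accession", "longest_run")], scans$motif)
  acc <- proteins$accession
  rows <- lapply(motifs, function(m) {
    L <- integer(length(acc))
    sub <- by_motif[[m]]
    if (!is.null(sub)) {
      idx <- match(sub$accession, acc)
      ok <- !is.na(idx)
      L[idx[ok]] <- sub$longest_run[ok]
    }
    ct <- categorize(L, proteins$in_condensate, eps_form)
    scr <- correlation_screen(ct, alpha)
    counts <- data.frame(
      t(stats::setNames(ct$N_ps, paste0("N_ps_", ct$x))),
      t(stats::setNames(ct$N_np, paste0("N_np_", ct$x))),
      t(stats::setNames(ct$f_ps, paste0("f_ps_", ct$x))))
    cbind(motif = m, scr, counts, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Size-matched resampling of the correlation screen
#'
#' Repeats the category/correlation analysis on random subsets in which every
#' category is downsampled without replacement to the size of the smallest
#' category, removing unequal-sample-size effects. Fully reproducible for a
#' fixed seed.
#'
#' @param longest_runs Per-protein longest run of the motif.
#' @param in_condensate Logical condensate labels.
#' @param n_subsets Number of resampling replicates (default 50).
#' @param seed Integer seed (required).
#' @param eps_form,alpha Passed to [categorize()] / [correlation_screen()].
#' @return data.frame with one row per replicate (`replicate`, `matched_n`,
#'   screen columns); the fraction of significant replicates is attached as
#'   attribute `"significant_fraction"`.
#' @export
size_matched_resample <- function(longest_runs, in_condensate,
                                  n_subsets = 50L, seed,
                                  eps_form = c("sqrt", "linear"),
                                  alpha = 0.05) {
  eps_form <- match.arg(eps_form)
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(n_subsets >= 1L)
  keep <- !is.na(longest_runs) & !is.na(in_condensate)
  L <- longest_runs[keep]; ps <- in_condensate[keep]
  members <- lapply(CATEGORY_X, function(x)
    which(if (x == 0L) L < 2L else L >= x))
  sizes <- lengths(members)
  m <- min(sizes)
  if (m < 3L) stop("smallest category has fewer than 3 proteins (", m, ")")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rows <- lapply(seq_len(n_subsets), function(rep_i) {
    ct <- do.call(rbind, lapply(seq_along(CATEGORY_X), function(k) {
      idx <- members[[k]]
      sub <- if (length(idx) > m) sample(idx, m) else idx
      fe <- fraction_and_error(sum(ps[sub]), sum(!ps[sub]), eps_form)
      data.frame(x = CATEGORY_X[k], cumulative = CATEGORY_X[k] > 0L,
                 N_ps = sum(ps[sub]), N_np = sum(!ps[sub]),
                 f_ps = fe$f_ps, E_ps = fe$E_ps)
    }))
    cbind(replicate = rep_i, matched_n = m, correlation_screen(ct, alpha))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "significant_fraction") <- mean(out$significant)
  out
}

# Save/restore the global RNG state so seeded operations do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
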