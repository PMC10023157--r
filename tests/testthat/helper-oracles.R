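# Independent oracles and small fixture builders shared across tests.
# Each oracle is a from-scratch route (regex, exhaustive enumeration,
# direct formula) that never calls the implementation it checks.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

random_sequence <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Maximal-run oracle: greedy regex over alternations (hetero-pair) or
# single-residue repeats (homo-pair). Returns lengths >= 2 with 0-based starts.
regex_runs_oracle <- function(sequence, motif) {
  m <- sort(strsplit(motif, "")[[1L]])
  pat <- if (m[1L] == m[2L]) paste0(m[1L], "{2,}")
         else paste0(m[1L], "(", m[2L], m[1L], ")*", m[2L], "?|",
                     m[2L], "(", m[1L], m[2L], ")*", m[1L], "?")
  hits <- gregexpr(pat, sequence, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(data.frame(start = integer(0), length = integer(0)))
  len <- attr(hits, "match.length")
  keep <- len >= 2L
  data.frame(start = as.integer(hits[keep]) - 1L, length = len[keep])
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins (probability-mass rule).
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]
  R1 <- sum(tab[1, ]); R2 <- sum(tab[2, ]); C1 <- sum(tab[, 1])
  if (sum(tab) == 0 || R1 == 0 || R2 == 0 || C1 == 0 || sum(tab[, 2]) == 0)
    return(1)
  support <- max(0, C1 - R2):min(R1, C1)
  probs <- stats::dhyper(support, R1, R2, C1)
  p_obs <- stats::dhyper(a, R1, R2, C1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mann-Whitney normal-approximation oracle with the *exact* permutation
# variance of U obtained by enumerating all assignments (valid for small n);
# with midrank ties this equals the tie-corrected variance.
mw_perm_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  U_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  Us <- apply(combos, 2, function(idx) sum(rk[idx]) - na * (na + 1) / 2)
  mu <- mean(Us)
  v <- mean((Us - mu)^2)
  p <- if (v == 0) 1 else 2 * stats::pnorm(-abs(U_obs - mu) / sqrt(v))
  list(U = U_obs, p = min(1, p))
}

# Exhaustive maximum-composition window oracle.
composition_oracle <- function(sequence, residue_set = c("R", "S"),
                               window = 20L) {
  chars <- strsplit(sequence, "")[[1L]]
  n <- length(chars)
  best <- -1; best_start <- NA_integer_
  for (i in seq_len(n - window + 1L)) {
    comp <- mean(chars[i:(i + window - 1L)] %in% residue_set)
    if (comp > best) { best <- comp; best_start <- i - 1L }
  }
  list(start = best_start, composition = best)
}

# Small labelled protein table for io/stats tests.
toy_protein_table <- function() {
  data.frame(
    accession = c("P1", "P2", "P3", "P4", "P5", "P6"),
    sequence = c("MRSRSRSRSRSRSRSRSA",  # 16-mer RS run
                 "MAAARSRSAAA",          # 4-mer
                 "MRSAAAAA",             # 2-mer
                 "MAAAAAAA",             # none
                 "MGGGGGGA",             # GG run
                 "MRSRSRAA"),            # 5-mer
    reviewed = TRUE, protein_evidence = TRUE,
    rrm_count = c(2L, 1L, 0L, 0L, 0L, 1L),
    in_condensate = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    source_dbs = c("db1", "db1,db2", "", "", "db3", ""),
    nonstandard_residues = FALSE,
    stringsAsFactors = FALSE)
}
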