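# Maximal dipeptide-repeat detection and composition-window scanning.

CANONICAL_AA <- c("A","C","D","E","F","G","H","I","K","L",
                  "M","N","P","Q","R","S","T","V","W","Y")

#' All unordered dipeptide motifs
#'
#' The 210 unordered residue pairs over the 20 canonical amino acids:
#' 190 hetero-pairs (e.g. `"RS"`, treated as interchangeable with `"SR"`)
#' plus 20 homo-pairs (e.g. `"GG"`, a mono-residue run).
#'
#' @return Character vector of length 210; each motif is the two residues in
#'   alphabetical order.
#' @export
all_dipeptide_motifs <- function() {
  idx <- which(upper.tri(matrix(0, 20, 20), diag = TRUE), arr.ind = TRUE)
  paste0(CANONICAL_AA[idx[, "row"]], CANONICAL_AA[idx[, "col"]])
}

# Normalize a motif given as "RS", "SR", c("R","S") to sorted two-residue form.
normalize_motif <- function(motif) {
  if (length(motif) == 1L) motif <- strsplit(motif, "")[[1L]]
  if (length(motif) != 2L || !all(motif %in% CANONICAL_AA))
    stop("motif must be an unordered pair of canonical residues, e.g. \"RS\"")
  paste(sort(motif), collapse = "")
}

# Adjacency validity for a motif: for hetero-pairs adjacent residues must be
# the two motif residues in either order (strict alternation); for homo-pairs
# both must equal the single residue. Non-canonical codes never match, so X/U/
# B/Z and sequence ends terminate runs.
motif_adjacency <- function(chars, motif) {
  n <- length(chars)
  if (n < 2L) return(logical(0))
  m <- strsplit(motif, "")[[1L]]
  a <- chars[-n]; b <- chars[-1L]
  if (m[1L] == m[2L]) a == m[1L] & b == m[1L]
  else (a == m[1L] & b == m[2L]) | (a == m[2L] & b == m[1L])
}

#' Find maximal uninterrupted dipeptide runs
#'
#' A run for a hetero-pair motif such as `"RS"` is a maximal substring
#' strictly alternating between the two residues; it may start and end with
#' either residue (an RS run and an SR run are the same thing, and counting
#' starts at the first residue of the run whichever of the two it is). For a
#' homo-pair motif such as `"GG"` a run is a maximal substring of that single
#' residue. Runs shorter than 2 residues are not reported.
#'
#' @param sequence Single protein sequence (one-letter codes, upper case).
#' @param motif Unordered residue pair, e.g. `"RS"`, `"SR"`, or `c("R","S")`.
#' @return A data.frame with columns `motif`, `start` (0-based), `length`
#'   (residues), and `span` (the matched substring), ordered by `start`.
#'   Zero rows when the sequence contains no run.
#' @examples
#' find_maximal_runs("SRSRSRSRC", "RS")   # one run of length 8 at start 0
#' find_maximal_runs("GGGGRSRS", "GR")    # the "GR" junction, length 2
#' @export
find_maximal_runs <- function(sequence, motif) {
  motif <- normalize_motif(motif)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "")[[1L]]
  valid <- motif_adjacency(chars, motif)
  empty <- data.frame(motif = character(0), start = integer(0),
                      length = integer(0), span = character(0),
                      stringsAsFactors = FALSE)
  if (!any(valid)) return(empty)
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L       # 1-based index into adjacency vector
  keep <- r$values
  run_start <- starts[keep]             # adjacency i joins residues i, i+1
  run_len <- r$lengths[keep] + 1L
  data.frame(
    motif = motif,
    start = run_start - 1L,             # 0-based residue coordinate
    length = run_len,
    span = substring(sequence, run_start, run_start + run_len - 1L),
    stringsAsFactors = FALSE
  )
}

#' Length of the longest uninterrupted run of a motif
#'
#' Only the longest maximal run matters for the repeat-length category
#' analysis; the number of runs is ignored there. Returns 0 when the motif
#' never occurs as a run of length >= 2.
#'
#' @inheritParams find_maximal_runs
#' @return Integer scalar.
#' @export
longest_run_length <- function(sequence, motif) {
  runs <- find_maximal_runs(sequence, motif)
  if (nrow(runs) == 0L) 0L else max(runs$length)
}

#' Count k-mer repeat units of a motif
#'
#' Two conventions are supported. `"tiling"` (default) tiles each maximal run
#' with non-overlapping k-mers and sums `floor(run_length / k)` over runs, so
#' a 16-residue run contributes four 4-mer units. `"runs"` counts the maximal
#' runs of length >= k, so the same 16-residue run contributes one.
#'
#' @inheritParams find_maximal_runs
#' @param k Even unit length >= 2.
#' @param convention `"tiling"` or `"runs"`.
#' @param run_lengths Optional integer vector of maximal run lengths; when
#'   supplied, `sequence`/`motif` are not consulted.
#' @return Integer count of units.
#' @export
count_kmer_units <- function(sequence = NULL, motif = NULL, k = 4L,
                             convention = c("tiling", "runs"),
                             run_lengths = NULL) {
  convention <- match.arg(convention)
  if (k < 2L || k %% 2L != 0L) stop("k must be an even integer >= 2")
  if (is.null(run_lengths))
    run_lengths <- find_maximal_runs(sequence, motif)$length
  if (length(run_lengths) == 0L) return(0L)
  if (convention == "tiling") as.integer(sum(run_lengths %/% k))
  else as.integer(sum(run_lengths >= k))
}

#' Scan one sequence for runs of every unordered dipeptide motif
#'
#' Every adjacent pair of canonical residues belongs to exactly one unordered
#' motif (the homo-pair when the residues are equal, the hetero-pair
#' otherwise), so a single pass over the adjacency classification recovers
#' the maximal runs of all 210 motifs at once. A residue may participate in
#' runs of different motifs ("GGGGRSRS" has a {G,R} run of 2 at the
#' junction as well as the {G,G} and {R,S} runs).
#'
#' @param sequence Single protein sequence.
#' @param include_empty If `TRUE`, also report motifs without any run
#'   (longest_run 0).
#' @param convention k-mer counting convention passed to
#'   [count_kmer_units()].
#' @return data.frame with one row per motif: `motif`, `longest_run`,
#'   `n_runs`, `unit_count_2`, `unit_count_4`.
#' @export
scan_all_motifs <- function(sequence, include_empty = FALSE,
                            convention = c("tiling", "runs")) {
  convention <- match.arg(convention)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "")[[1L]]
  n <- length(chars)
  empty <- data.frame(motif = character(0), longest_run = integer(0),
                      n_runs = integer(0), unit_count_2 = integer(0),
                      unit_count_4 = integer(0), stringsAsFactors = FALSE)
  out <- empty
  if (n >= 2L) {
    a <- chars[-n]; b <- chars[-1L]
    lo <- pmin(a, b); hi <- pmax(a, b)
    id <- paste0(lo, hi)
    id[!(a %in% CANONICAL_AA & b %in% CANONICAL_AA)] <- NA_character_
    r <- rle(id)
    keep <- !is.na(r$values)
    if (any(keep)) {
      motif <- r$values[keep]
      len <- r$lengths[keep] + 1L     # adjacencies -> residues
      agg <- split(len, motif)
      out <- data.frame(
        motif = names(agg),
        longest_run = vapply(agg, max, integer(1)),
        n_runs = vapply(agg, length, integer(1)),
        unit_count_2 = vapply(agg, function(l)
          count_kmer_units(run_lengths = l, k = 2L, convention = convention),
          integer(1)),
        unit_count_4 = vapply(agg, function(l)
          count_kmer_units(run_lengths = l, k = 4L, convention = convention),
          integer(1)),
        row.names = NULL, stringsAsFactors = FALSE
      )
    }
  }
  if (include_empty) {
    missing <- setdiff(all_dipeptide_motifs(), out$motif)
    if (length(missing)) {
      out <- rbind(out, data.frame(
        motif = missing, longest_run = 0L, n_runs = 0L,
        unit_count_2 = 0L, unit_count_4 = 0L, stringsAsFactors = FALSE))
    }
  }
  out[order(out$motif), , drop = FALSE]
}

#' Scan a protein table for dipeptide repeats
#'
#' @param proteins data.frame with at least `accession` and `sequence`
#'   columns (see [build_protein_table()]).
#' @param motifs `"all"` or a character vector of motifs (e.g.
#'   `c("RS","RG")`).
#' @param convention k-mer counting convention, see [count_kmer_units()].
#' @return Long-format data.frame (`accession`, `motif`, `longest_run`,
#'   `n_runs`, `unit_count_2`, `unit_count_4`) containing only motifs with at
#'   least one run; proteins with no run of a motif are implicitly in its
#'   x = 0 category.
#' @export
scan_proteins <- function(proteins, motifs = "all",
                          convention = c("tiling", "runs")) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(proteins),
            all(c("accession", "sequence") %in% names(proteins)))
  empty <- data.frame(accession = character(0), motif = character(0),
                      longest_run = integer(0), n_runs = integer(0),
                      unit_count_2 = integer(0), unit_count_4 = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(proteins) == 0L) return(empty)
  # single pass over the concatenated proteome: sequences are joined with a
  # non-residue separator (which, like any non-canonical code, terminates
  # runs), every adjacency is classified into its unordered motif, and one
  # rle recovers all maximal runs of all motifs at once
  chars <- strsplit(paste(proteins$sequence, collapse = "|"), "")[[1L]]
  n <- length(chars)
  if (n < 2L) return(empty)
  a <- chars[-n]; b <- chars[-1L]
  id <- paste0(pmin(a, b), pmax(a, b))
  id[!(a %in% CANONICAL_AA & b %in% CANONICAL_AA)] <- NA_character_
  r <- rle(id)
  keep <- !is.na(r$values)
  if (!any(keep)) return(empty)
  run_end <- cumsum(r$lengths)                 # adjacency index of run end
  run_start <- run_end - r$lengths + 1L
  motif <- r$values[keep]
  len <- r$lengths[keep] + 1L                  # adjacencies -> residues
  # map run starts back to proteins via the character offsets of each record
  seq_start <- cumsum(c(1L, nchar(proteins$sequence) + 1L))  # incl. separator
  pidx <- findInterval(run_start[keep], seq_start)
  key <- paste0(pidx, "\r", motif)
  f <- factor(key)
  li <- as.integer(f)
  ord <- order(li, -len)
  first <- !duplicated(li[ord])
  longest <- integer(nlevels(f)); longest[li[ord][first]] <- len[ord][first]
  n_runs <- tabulate(li, nbins = nlevels(f))
  u2 <- as.integer(rowsum(len %/% 2L, li)[, 1L])
  u4 <- as.integer(rowsum(len %/% 4L, li)[, 1L])
  if (convention == "runs") {
    u2 <- as.integer(rowsum(as.integer(len >= 2L), li)[, 1L])
    u4 <- as.integer(rowsum(as.integer(len >= 4L), li)[, 1L])
  }
  parts <- strsplit(levels(f), "\r", fixed = TRUE)
  out <- data.frame(
    accession = proteins$accession[as.integer(vapply(parts, `[`, character(1), 1L))],
    motif = vapply(parts, `[`, character(1), 2L),
    longest_run = longest, n_runs = n_runs,
    unit_count_2 = u2, unit_count_4 = u4,
    stringsAsFactors = FALSE)
  if (!identical(motifs, "all")) {
    motifs <- vapply(motifs, normalize_motif, character(1))
    out <- out[out$motif %in% motifs, , drop = FALSE]
  }
  out <- out[order(match(out$accession, proteins$accession), out$motif), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-protein longest-run vector for one motif
#'
#' Convenience accessor over a [scan_proteins()] result: longest run of
#' `motif` for every accession in `accessions`, 0 for proteins without a run.
#'
#' @param scans data.frame from [scan_proteins()].
#' @param accessions Character vector defining the output order.
#' @param motif Unordered dipeptide motif.
#' @return Integer vector aligned with `accessions`.
#' @export
longest_runs_for_motif <- function(scans, accessions, motif) {
  motif <- normalize_motif(motif)
  sub <- scans[scans$motif == motif, , drop = FALSE]
  out <- integer(length(accessions))
  idx <- match(sub$accession, accessions)
  ok <- !is.na(idx)
  out[idx[ok]] <- sub$longest_run[ok]
  out
}

#' Maximum-composition window of a residue set
#'
#' Slides a fixed-length window along the sequence and reports the window
#' with the highest fraction of residues belonging to `residue_set`
#' (ties broken by the earliest start). The hit is reported only when that
#' maximum meets `threshold`; a protein therefore yields at most one hit,
#' matching the single-hit rule of low-complexity composition searches.
#'
#' @param sequence Protein sequence.
#' @param residue_set Residues counted toward the composition
#'   (default R and S).
#' @param window Window length in residues (default 20).
#' @param threshold Minimum composition fraction for a hit (default 0.40).
#' @return One-row data.frame (`window_start` 0-based, `window_length`,
#'   `composition`, `span`), or `NULL` when no window qualifies or the
#'   sequence is shorter than the window (with a warning).
#' @export
composition_windows <- function(sequence, residue_set = c("R", "S"),
                                window = 20L, threshold = 0.40) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            window >= 1L, threshold >= 0, threshold <= 1)
  chars <- strsplit(sequence, "")[[1L]]
  n <- length(chars)
  if (n < window) {
    warning("sequence shorter than window (", n, " < ", window, ")")
    return(NULL)
  }
  ind <- as.integer(chars %in% residue_set)
  cs <- c(0L, cumsum(ind))
  counts <- cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]
  best <- which.max(counts)                 # earliest maximum
  comp <- counts[best] / window
  if (comp < threshold) return(NULL)
  data.frame(window_start = best - 1L, window_length = as.integer(window),
             composition = comp,
             span = substring(sequence, best, best + window - 1L),
             stringsAsFactors = FALSE)
}
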