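# Ingestion of protein sequences, annotations and condensate-membership
# lists into a unified labelled protein table.

#' Read protein sequences from FASTA
#'
#' Accessions are taken from the first whitespace-delimited token of each
#' header; UniProt pipe-delimited headers (`sp|Q07955|SRSF1_HUMAN`) are
#' reduced to the accession field. Wrapped sequence lines are concatenated.
#'
#' @param path Path to a FASTA file.
#' @return data.frame with columns `accession` and `sequence` (upper case),
#'   in file order.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  headers <- names(set)
  acc <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  piped <- grepl("\\|", acc)
  acc[piped] <- vapply(strsplit(acc[piped], "\\|", fixed = FALSE),
                       function(x) if (length(x) >= 2L) x[2L] else x[1L],
                       character(1))
  zero <- Biostrings::width(set) == 0L
  if (any(zero))
    stop("zero-length sequence for record(s): ",
         paste(acc[zero], collapse = ", "))
  bad <- is.na(acc) | acc == ""
  if (any(bad))
    stop("malformed FASTA header for record(s) at position(s): ",
         paste(which(bad), collapse = ", "))
  data.frame(accession = acc,
             sequence = toupper(as.character(set)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# TRUE/FALSE interpretation for annotation flag columns that may arrive as
# logicals, 0/1, "reviewed"/"unreviewed" or evidence-level strings.
parse_flag <- function(x, truthy_regex) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  x <- tolower(trimws(as.character(x)))
  x %in% c("true", "t", "yes", "1") | grepl(truthy_regex, x)
}

#' Parse a protein annotation table
#'
#' Reads a TSV (header row required) with per-accession annotation:
#' an accession column, a reviewed flag, a protein-level-evidence flag and an
#' RRM-domain feature column. The RRM column may hold a count or a feature
#' string, in which case occurrences of "RRM" are counted. A missing RRM
#' column yields `rrm_count = 0` with a warning.
#'
#' @param path Path to a tab-delimited annotation file.
#' @return data.frame keyed by `accession` with logical `reviewed`,
#'   logical `protein_evidence` and integer `rrm_count`.
#' @export
parse_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "")
  nm <- tolower(names(tab))
  pick <- function(candidates) {
    hit <- which(nm %in% candidates)
    if (length(hit)) hit[1L] else NA_integer_
  }
  acc_col <- pick(c("accession", "entry", "acc"))
  if (is.na(acc_col)) stop("annotation table lacks an accession column")
  acc <- as.character(tab[[acc_col]])
  dup <- unique(acc[duplicated(acc)])
  if (length(dup))
    stop("duplicate accessions in annotation table: ",
         paste(dup, collapse = ", "))
  rev_col <- pick(c("reviewed", "status"))
  evi_col <- pick(c("protein_evidence", "evidence", "protein existence"))
  rrm_col <- which(grepl("rrm", nm))
  reviewed <- if (is.na(rev_col)) rep(TRUE, length(acc))
              else parse_flag(tab[[rev_col]], "^reviewed")
  evidence <- if (is.na(evi_col)) rep(TRUE, length(acc))
              else parse_flag(tab[[evi_col]], "protein level")
  if (length(rrm_col) == 0L) {
    warning("no RRM feature column found; rrm_count set to 0")
    rrm <- rep(0L, length(acc))
  } else {
    raw <- tab[[rrm_col[1L]]]
    num <- suppressWarnings(as.integer(raw))
    rrm <- ifelse(!is.na(num), num,
                  vapply(gregexpr("RRM", as.character(raw), fixed = TRUE),
                         function(m) sum(m > 0L), integer(1)))
    rrm[is.na(rrm)] <- 0L
  }
  if (any(rrm < 0L)) stop("negative RRM counts in annotation table")
  data.frame(accession = acc, reviewed = reviewed,
             protein_evidence = evidence, rrm_count = as.integer(rrm),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Strip isoform suffixes from accessions
#'
#' `"P05067-2"` becomes `"P05067"`; accessions without a suffix pass through.
#'
#' @param accessions Character vector.
#' @return Character vector of the same length.
#' @export
strip_isoform <- function(accessions) sub("-\\d+$", "", accessions)

#' Load condensate-membership accession lists
#'
#' Each file is a newline-delimited accession list exported from one
#' phase-separation database. Membership is the union across databases;
#' isoform suffixes are stripped before matching. Per-database provenance is
#' retained.
#'
#' @param paths Character vector of file paths.
#' @param db_names Database names; defaults to file base names.
#' @return data.frame with `accession` and `source_dbs` (comma-separated
#'   provenance). A warning (not an error) is raised when the union is empty.
#' @export
load_condensate_lists <- function(paths, db_names = NULL) {
  paths <- as.character(unlist(paths))
  if (is.null(db_names)) db_names <- tools::file_path_sans_ext(basename(paths))
  stopifnot(length(db_names) == length(paths))
  per_db <- lapply(seq_along(paths), function(i) {
    if (!file.exists(paths[i])) stop("condensate list not found: ", paths[i])
    acc <- readLines(paths[i], warn = FALSE)
    acc <- trimws(acc)
    unique(strip_isoform(acc[nzchar(acc)]))
  })
  names(per_db) <- db_names
  all_acc <- sort(unique(unlist(per_db)))
  if (length(all_acc) == 0L) {
    warning("union of condensate lists is empty")
    return(data.frame(accession = character(0), source_dbs = character(0),
                      stringsAsFactors = FALSE))
  }
  prov <- vapply(all_acc, function(a)
    paste(db_names[vapply(per_db, function(s) a %in% s, logical(1))],
          collapse = ","), character(1))
  data.frame(accession = all_acc, source_dbs = unname(prov),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the unified labelled protein table
#'
#' Joins sequences, annotations and condensate membership into one table of
#' protein records, applying the reviewed / protein-level-evidence filters
#' used to restrict a proteome to full-length, reviewed entries with protein
#' evidence. One sequence per accession (canonical isoform); duplicate
#' accessions in the FASTA are rejected. Annotated accessions absent from
#' the FASTA are skipped with a warning. Excluded-record counts are reported
#' via `message()`.
#'
#' @param fasta data.frame from [read_protein_fasta()].
#' @param annotations data.frame from [parse_annotations()], or `NULL` for
#'   all-reviewed defaults with `rrm_count = 0`.
#' @param condensate data.frame from [load_condensate_lists()], or `NULL`.
#' @param reviewed_only Drop records not flagged reviewed (default `TRUE`).
#' @param evidence_only Drop records without protein-level evidence
#'   (default `TRUE`).
#' @return data.frame of protein records: `accession`, `sequence`,
#'   `reviewed`, `protein_evidence`, `rrm_count`, `in_condensate`,
#'   `source_dbs`, `nonstandard_residues` (flag for codes outside the 20
#'   canonical letters; such codes are retained in the sequence but
#'   terminate repeat runs).
#' @export
build_protein_table <- function(fasta, annotations = NULL, condensate = NULL,
                                reviewed_only = TRUE, evidence_only = TRUE) {
  stopifnot(is.data.frame(fasta),
            all(c("accession", "sequence") %in% names(fasta)))
  dup <- unique(fasta$accession[duplicated(fasta$accession)])
  if (length(dup))
    stop("multiple sequences (isoforms?) for accession(s): ",
         paste(dup, collapse = ", "), "; supply one canonical isoform each")
  tab <- fasta
  if (!is.null(annotations)) {
    missing_seq <- setdiff(annotations$accession, fasta$accession)
    if (length(missing_seq))
      warning(length(missing_seq),
              " annotated accession(s) absent from FASTA; skipped")
    idx <- match(tab$accession, annotations$accession)
    tab$reviewed <- annotations$reviewed[idx]
    tab$protein_evidence <- annotations$protein_evidence[idx]
    tab$rrm_count <- annotations$rrm_count[idx]
    tab$reviewed[is.na(tab$reviewed)] <- FALSE
    tab$protein_evidence[is.na(tab$protein_evidence)] <- FALSE
    tab$rrm_count[is.na(tab$rrm_count)] <- 0L
  } else {
    tab$reviewed <- TRUE
    tab$protein_evidence <- TRUE
    tab$rrm_count <- 0L
  }
  n0 <- nrow(tab)
  if (reviewed_only) tab <- tab[tab$reviewed, , drop = FALSE]
  if (evidence_only) tab <- tab[tab$protein_evidence, , drop = FALSE]
  if (nrow(tab) < n0)
    message(n0 - nrow(tab), " record(s) excluded by reviewed/evidence filters")
  if (!is.null(condensate) && nrow(condensate)) {
    idx <- match(strip_isoform(tab$accession), condensate$accession)
    tab$in_condensate <- !is.na(idx)
    tab$source_dbs <- ifelse(tab$in_condensate, condensate$source_dbs[idx], "")
  } else {
    tab$in_condensate <- FALSE
    tab$source_dbs <- ""
  }
  pattern <- paste0("[^", paste(CANONICAL_AA, collapse = ""), "]")
  tab$nonstandard_residues <- grepl(pattern, tab$sequence)
  rownames(tab) <- NULL
  tab
}

#' Write / read the protein table as TSV
#'
#' Plain tab-delimited serialization; `read_protein_table()` restores all
#' column types so that a write/read round trip reproduces the table exactly.
#'
#' @param table Protein table from [build_protein_table()].
#' @param path Output (input) TSV path.
#' @return `write_protein_table()` returns `path` invisibly;
#'   `read_protein_table()` returns the table.
#' @export
write_protein_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_protein_table
#' @export
read_protein_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "",
                           colClasses = c(
                             accession = "character", sequence = "character",
                             reviewed = "logical",
                             protein_evidence = "logical",
                             rrm_count = "integer", in_condensate = "logical",
                             source_dbs = "character",
                             nonstandard_residues = "logical"))
  tab$source_dbs[is.na(tab$source_dbs)] <- ""
  tab
}
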