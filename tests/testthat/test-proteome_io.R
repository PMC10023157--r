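write_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

test_that("FASTA parsing: headers, order, wrapped lines, failures", {
  p <- write_tmp(c(">sp|Q07955|SRSF1_HUMAN some description",
                   "MSGGG", "VVRGP",
                   ">P12345 plain accession", "ACDEF"), ".fasta")
  tab <- read_protein_fasta(p)
  expect_equal(tab$accession, c("Q07955", "P12345"))
  expect_equal(tab$sequence[1L], "MSGGGVVRGP")

  p2 <- write_tmp(c(">A", "ACD", ">B", "", ">C", "ACD"), ".fasta")
  expect_error(read_protein_fasta(p2), "zero-length.*B")
  expect_error(read_protein_fasta(tempfile()), "not found")
})

test_that("annotation parsing: RRM counts, missing column, duplicates", {
  p <- write_tmp(c("accession\treviewed\tprotein_evidence\trrm_count",
                   "P1\tTRUE\tTRUE\t2",
                   "P2\treviewed\tEvidence at protein level\t0"))
  ann <- parse_annotations(p)
  expect_equal(ann$rrm_count, c(2L, 0L))
  expect_true(all(ann$reviewed) && all(ann$protein_evidence))

  # feature-string RRM column
  p2 <- write_tmp(c("accession\trrm_domains",
                    "P1\tRRM 1; RRM 2; RRM 3", "P2\t"))
  ann2 <- parse_annotations(p2)
  expect_equal(ann2$rrm_count, c(3L, 0L))

  p3 <- write_tmp(c("accession\treviewed", "P1\tTRUE"))
  expect_warning(ann3 <- parse_annotations(p3), "RRM")
  expect_equal(ann3$rrm_count, 0L)

  p4 <- write_tmp(c("accession\trrm_count", "P1\t1", "P1\t2"))
  expect_error(parse_annotations(p4), "duplicate.*P1")
})

test_that("condensate lists: union, provenance, isoform stripping", {
  pa <- write_tmp(c("A", "B"))
  pb <- write_tmp(c("B", "C"))
  pc <- write_tmp(character(0))
  cond <- load_condensate_lists(c(pa, pb, pc), c("db1", "db2", "db3"))
  expect_setequal(cond$accession, c("A", "B", "C"))
  expect_equal(cond$source_dbs[cond$accession == "B"], "db1,db2")

  iso <- load_condensate_lists(write_tmp("P05067-2"), "db1")
  expect_equal(iso$accession, "P05067")

  expect_warning(
    empty <- load_condensate_lists(write_tmp(character(0)), "db1"),
    "empty")
  expect_equal(nrow(empty), 0L)

  # three disjoint singletons
  singles <- load_condensate_lists(
    c(write_tmp("X"), write_tmp("Y"), write_tmp("Z")), c("a", "b", "c"))
  expect_equal(nrow(singles), 3L)
})

test_that("protein table assembly: filters, labels, round trip", {
  fasta <- data.frame(
    accession = paste0("P", 1:5),
    sequence = c("MRSRSRSRSA", "MAARSRSAA", "MAAAA", "MGGGGA", "MRSA"),
    stringsAsFactors = FALSE)
  ann <- data.frame(accession = paste0("P", c(1:5, 9)),
                    reviewed = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
                    protein_evidence = TRUE,
                    rrm_count = c(2L, 0L, 0L, 1L, 0L, 0L),
                    stringsAsFactors = FALSE)
  cond <- data.frame(accession = c("P2", "P9"), source_dbs = "db1",
                     stringsAsFactors = FALSE)
  expect_warning(
    expect_message(tab <- build_protein_table(fasta, ann, cond),
                   "excluded"),
    "absent from FASTA")
  expect_equal(tab$accession, c("P1", "P2", "P4"))   # 2 unreviewed dropped
  expect_equal(tab$in_condensate, c(FALSE, TRUE, FALSE))
  expect_equal(tab$rrm_count, c(2L, 0L, 1L))

  # no filters -> everything retained
  all_tab <- suppressWarnings(
    build_protein_table(fasta, ann, cond, reviewed_only = FALSE,
                        evidence_only = FALSE))
  expect_equal(nrow(all_tab), 5L)

  # isoform accession in a condensate list matches the base accession
  cond2 <- load_condensate_lists(write_tmp("P4-2"), "db1")
  tab2 <- build_protein_table(fasta, NULL, cond2)
  expect_true(tab2$in_condensate[tab2$accession == "P4"])

  # exact TSV round trip
  p <- tempfile(fileext = ".tsv")
  write_protein_table(tab, p)
  expect_identical(read_protein_table(p), tab)

  # duplicate accessions in FASTA are rejected
  expect_error(build_protein_table(rbind(fasta, fasta[1, ])), "isoform")
})

test_that("adding a database list never unsets condensate membership", {
  fasta <- data.frame(accession = paste0("P", 1:6),
                      sequence = strrep("MARS", 5),
                      stringsAsFactors = FALSE)
  set.seed(5)
  lists <- lapply(1:3, function(i)
    write_tmp(sample(fasta$accession, sample(0:4, 1))))
  prev <- rep(FALSE, 6)
  for (k in 1:3) {
    cond <- suppressWarnings(load_condensate_lists(lists[seq_len(k)]))
    tab <- build_protein_table(fasta, NULL, cond)
    expect_true(all(tab$in_condensate[prev]))
    prev <- tab$in_condensate
  }
})
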