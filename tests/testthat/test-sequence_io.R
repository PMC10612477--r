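test_that("read_fasta parses records in order, concatenates lines, folds case", {
  d <- withr::local_tempdir()
  p <- file.path(d, "a.fasta")
  writeLines(c(">a", "ACG", "t", ">b desc text", "TTT"), p)
  x <- read_fasta(p)
  expect_equal(unname(x), c("ACGT", "TTT"))
  expect_equal(names(x), c("a", "b desc text"))
})

test_that("read_fasta rejects missing files, duplicates, and empty records", {
  d <- withr::local_tempdir()
  expect_error(read_fasta(file.path(d, "nope.fasta")), "not found")
  p <- file.path(d, "dup.fasta")
  writeLines(c(">a", "ACG", ">a", "TTT"), p)
  expect_error(read_fasta(p), "duplicate")
  p2 <- file.path(d, "empty.fasta")
  writeLines(c(">a", ">b", "TTT"), p2)
  expect_error(read_fasta(p2), "empty")
})

test_that("fasta round trip preserves header/sequence multisets and gzip reads", {
  d <- withr::local_tempdir()
  seqs <- c(g1 = "ATGGCTAAA", g2 = paste(rep("ACGT", 40), collapse = ""))
  p <- file.path(d, "rt.fasta")
  write_fasta(seqs, p, width = 13)
  expect_equal(read_fasta(p), seqs)
  gz <- file.path(d, "rt.fasta.gz")
  con <- gzfile(gz, "w"); writeLines(c(">g1", "ATGGCTAAA"), con); close(con)
  expect_equal(read_fasta(gz), c(g1 = "ATGGCTAAA"))
})

test_that("translate_cds follows the universal code with the N rule", {
  expect_equal(translate_cds("ATGGCT"), "MA")
  expect_equal(translate_cds("ATGNNN"), "MX")
  expect_equal(translate_cds("atgaat"), "MN")
  expect_equal(translate_cds("TAA"), "*")
  expect_error(translate_cds("ATGGC"), "divisible")
})

test_that("pair_and_validate strips terminal stops and accepts clean records", {
  d <- withr::local_tempdir()
  cds <- tmp_fasta(c(g1 = "ATGGCTTAA", g2 = "ATGAATGGA"), d)
  pep <- tmp_fasta(c(g1 = "MA", g2 = "MNG"), d)
  pp <- pair_and_validate(cds, pep, "sp1")
  expect_s3_class(pp, "proteome_pair")
  expect_equal(nrow(pp$records), 2L)
  expect_equal(pp$records$cds[pp$records$header == "g1"], "ATGGCT")
  expect_equal(nrow(pp$rejected), 0L)
})

test_that("header-set mismatch and count mismatch are fatal", {
  d <- withr::local_tempdir()
  cds <- tmp_fasta(c(g1 = "ATGGCTTAA", g2 = "ATGAAT"), d)
  pep <- tmp_fasta(c(g1 = "MA", g3 = "MN"), d)
  expect_error(pair_and_validate(cds, pep, "sp1"), "header sets differ")
  pep2 <- tmp_fasta(c(g1 = "MA"), d)
  expect_error(pair_and_validate(cds, pep2, "sp1"), "counts differ")
})

test_that("per-record failures are rejected with machine-readable reasons", {
  d <- withr::local_tempdir()
  cds <- tmp_fasta(c(ok = "ATGGCTTAA", stp = "ATGTAAGCT", frame = "ATGGC",
                     mism = "ATGGGT"), d)
  pep <- tmp_fasta(c(ok = "MA", stp = "M?A", frame = "M", mism = "MA"), d)
  pp <- pair_and_validate(cds, pep, "sp1")
  expect_equal(pp$records$header, "ok")
  rej <- setNames(pp$rejected$reason, pp$rejected$header)
  expect_equal(rej[["stp"]], "internal_stop")
  expect_equal(rej[["frame"]], "frame_error")
  expect_equal(rej[["mism"]], "translation_mismatch")
})

test_that("validation is insensitive to record order and X matches any residue", {
  d <- withr::local_tempdir()
  cds_seqs <- c(g1 = "ATGGCTTAA", g2 = "ATGNATTAA", g3 = "ATGTTTTAA")
  pep_seqs <- c(g1 = "MA", g2 = "MX", g3 = "MF")
  a <- pair_and_validate(tmp_fasta(cds_seqs, d), tmp_fasta(pep_seqs, d), "s")
  perm <- c("g3", "g1", "g2")
  b <- pair_and_validate(tmp_fasta(cds_seqs[perm], d),
                         tmp_fasta(pep_seqs[perm], d), "s")
  expect_setequal(a$records$header, b$records$header)
  expect_equal(a$records[order(a$records$header), ],
               b$records[order(b$records$header), ],
               ignore_attr = TRUE)
  expect_true("g2" %in% a$records$header)  # X wildcard accepted
})

test_that("load_proteomes pairs files by stem and writes a validation report", {
  d <- withr::local_tempdir()
  dir.create(file.path(d, "cds")); dir.create(file.path(d, "pep"))
  for (sp in c("alpha", "beta")) {
    write_fasta(c(g1 = "ATGGCTTAA"), file.path(d, "cds", paste0(sp, ".fasta")))
    write_fasta(c(g1 = "MA"), file.path(d, "pep", paste0(sp, ".fasta")))
  }
  pr <- load_proteomes(file.path(d, "cds"), file.path(d, "pep"))
  expect_setequal(names(pr), c("alpha", "beta"))
  rep_path <- file.path(d, "report.tsv")
  write_validation_report(pr, rep_path)
  rep <- read.table(rep_path, sep = "\t", header = TRUE)
  expect_equal(nrow(rep), 2L)
  expect_true(all(rep$status == "ok"))
})
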