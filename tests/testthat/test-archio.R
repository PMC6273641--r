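test_that("read_fasta reads records in file order with case folding", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKT", ">b", "GHS"), fa)
  rec <- read_fasta(fa)
  expect_equal(rec$id, c("a", "b"))
  expect_equal(rec$gene_order_index, c(0L, 1L))
  expect_equal(rec$sequence, c("MKT", "GHS"))

  writeLines(c(">a", "mkt"), fa)
  expect_equal(read_fasta(fa)$sequence, "MKT")

  writeLines(c(">ThaBI", "MKT", ">ThaBII", "GAS", ">ThaBIII", "LVT",
               ">ThaBIV", "AAC"), fa)
  rec <- read_fasta(fa)
  expect_equal(rec$id, c("ThaBI", "ThaBII", "ThaBIII", "ThaBIV"))
  expect_equal(rec$gene_order_index, 0:3)
})

test_that("read_fasta errors on empty input and warns on odd characters", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), fa)
  expect_error(read_fasta(fa), "no records")
  writeLines(c(">a", "MKTB"), fa)
  expect_warning(rec <- read_fasta(fa), "unexpected characters")
  expect_equal(rec$sequence, "MKTB")  # kept, not dropped
})

test_that("FASTA write/read round-trip preserves sequences byte-exactly", {
  recs <- generate_cluster(random_module_plan(3), seed = 9)$proteins
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, fa)
  back <- read_fasta(fa)
  expect_identical(back$sequence, recs$sequence)
  expect_identical(back$id, recs$id)
})

test_that("the published architecture string parses to 14 module groups", {
  expect_equal(nrow(tha_arch$proteins), 4L)
  expect_equal(sum(lengths(tha_arch$groups)), 14L)
  # TE only in the last group of the last protein
  te_in <- unlist(lapply(tha_arch$groups, function(gs) {
    vapply(gs, function(g) "TE" %in% g, logical(1))
  }))
  expect_equal(which(te_in), 14L)
  # docking placement as printed: ThaBI has no N-terminal dock
  expect_equal(tha_arch$proteins$n_term_dock, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(tha_arch$proteins$c_term_dock, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("minimal architecture parses without docks", {
  a <- parse_architecture("P [(KS-AT-ACP)]")
  expect_equal(nrow(a$proteins), 1L)
  expect_length(a$groups[[1]], 1L)
  expect_false(a$proteins$n_term_dock)
  expect_false(a$proteins$c_term_dock)
})

test_that("architecture parse errors carry position and token information", {
  expect_error(parse_architecture("P [(KS-AT-ACP]"), "parenthes")
  expect_error(parse_architecture("P [(KS-XX-ACP)]"), "XX")
  expect_error(parse_architecture("P [(KS-AT-ACP)"), "bracket")
  expect_error(parse_architecture(""), "empty")
})

test_that("parse/print round-trips on fuzzed grammar strings", {
  for (seed in 1:50) {
    s <- random_architecture_string(seed)
    parsed <- parse_architecture(s)
    expect_identical(format(parsed), s, label = paste("seed", seed))
    expect_identical(format(parse_architecture(format(parsed))), s)
  }
})

test_that("reports serialize deterministically and round-trip", {
  line <- segment_modules(architecture_to_hits(tha_arch))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_report(line, f1, "json")
  write_report(line, f2, "json")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_report(f1)
  expect_length(back$modules$module_index, 14L)
  expect_identical(back$architecture, format(line_to_architecture(line)))

  ftsv <- withr::local_tempfile(fileext = ".tsv")
  write_report(line, ftsv, "tsv")
  tab <- readr::read_tsv(ftsv, show_col_types = FALSE)
  expect_equal(nrow(tab), 14L)
})

test_that("product reports round-trip through JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  write_report(tha_product, f, "json")
  back <- read_report(f)
  feat <- compute_features(tha_product)
  expect_identical(back$formula, feat$formula)
  expect_equal(back$monoisotopic_mass, feat$monoisotopic_mass,
               tolerance = 1e-6)
  expect_identical(unlist(back$free_hydroxyl_positions),
                   tha_product$free_hydroxyl_positions)
})

test_that("interval tables validate coordinates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    cluster_id = "c1", contig_id = "x", start = 10L, end = 5L
  ), f)
  expect_error(read_interval_table(f), "start < end")
})
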