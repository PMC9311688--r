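test_that("GenBank round-trip recovers replicons, elements and strands exactly", {
  spec <- small_cohort_spec(seed = 5, n_pos = 2, n_neg = 1,
                            n_test_pos = 0, n_test_neg = 0)
  dir <- withr::local_tempdir()
  coh <- generate_cohort(spec, dir = dir)
  for (g in coh$genomes) {
    rd <- read_genbank(file.path(dir, paste0(g$organism_id, ".gbk")))
    expect_identical(rd$replicons, g$replicons)
    expect_identical(rd$elements[, names(rd$elements)],
                     g$elements[, names(rd$elements)])
    # per-class concatenation lengths match what the generator planted
    for (cls in c("CDS", "rRNA", "tRNA", "ncRNA")) {
      expect_identical(nchar(concatenate_class(rd, cls)),
                       sum(nchar(g$elements$sequence[
                         g$elements$element_class == cls])))
    }
  }
})

test_that("minus-strand elements come back reverse-complemented", {
  g <- toy_genome(replicons = c(chr = "AACCGGTTACGTACGT"),
                  elements = data.frame(
                    replicon = "chr", element_class = c("CDS", "tRNA"),
                    start = c(0L, 8L), end = c(4L, 12L),
                    strand = c("+", "-"),
                    sequence = c("AACC", revcomp_base("ACGT")),
                    stringsAsFactors = FALSE))
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(g, path)
  rd <- read_genbank(path)
  expect_equal(nrow(rd$elements), 2L)
  trna <- rd$elements[rd$elements$element_class == "tRNA", ]
  expect_identical(trna$sequence, revcomp_base(substr("AACCGGTTACGTACGT", 9, 12)))
  # double reverse complement returns the original span
  expect_identical(revcomp_base(trna$sequence),
                   substr("AACCGGTTACGTACGT", 9, 12))
})

test_that("compound and partial locations are parsed", {
  gb <- c(
    "LOCUS       TESTREC              24 bp    DNA     linear BCT 01-JAN-2022",
    "FEATURES             Location/Qualifiers",
    "     source          1..24",
    "     CDS             join(1..6,13..18)",
    "                     /locus_tag=\"j1\"",
    "     CDS             complement(join(7..9,19..21))",
    "     tRNA            <2..>10",
    "     rRNA            5",
    "ORIGIN",
    "        1 aaacccgggt ttacgtacgt acgt",
    "//")
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gb, path)
  g <- read_genbank(path)
  s <- toupper("aaacccgggtttacgtacgtacgt")
  expect_equal(g$elements$sequence[1], paste0(substr(s, 1, 6), substr(s, 13, 18)))
  expect_equal(g$elements$sequence[2],
               revcomp_base(paste0(substr(s, 7, 9), substr(s, 19, 21))))
  expect_equal(g$elements$sequence[3], substr(s, 2, 10))  # partial markers dropped
  expect_equal(g$elements$sequence[4], substr(s, 5, 5))   # single-base location
  expect_equal(g$elements$strand, c("+", "-", "+", "+"))
})

test_that("multi-record files yield one genome with several replicons", {
  spec <- small_cohort_spec(seed = 9, n_pos = 6, n_neg = 0,
                            n_test_pos = 0, n_test_neg = 0)
  spec$plasmid_prob <- 1
  dir <- withr::local_tempdir()
  coh <- generate_cohort(spec, dir = dir)
  g <- read_genbank(file.path(dir, paste0(coh$genomes[[1]]$organism_id, ".gbk")))
  expect_length(g$replicons, 2L)
  expect_setequal(unique(g$elements$replicon), names(g$replicons))
  for (i in seq_len(nrow(g$elements))) {
    e <- g$elements[i, ]
    expect_lte(e$end, nchar(g$replicons[[e$replicon]]))
  }
})

test_that("annotation-free and malformed files are handled", {
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       EMPTYREC              8 bp    DNA     linear",
               "FEATURES             Location/Qualifiers",
               "     source          1..8",
               "ORIGIN",
               "        1 acgtacgt",
               "//"), path)
  expect_warning(g <- read_genbank(path), "no CDS/rRNA/tRNA/ncRNA")
  expect_equal(nrow(g$elements), 0L)

  writeLines(c("LOCUS       BADREC              8 bp",
               "FEATURES             Location/Qualifiers",
               "     CDS             4..banana",
               "ORIGIN",
               "        1 acgtacgt",
               "//"), path)
  expect_error(read_genbank(path), "BADREC")
  expect_error(read_genbank(file.path(tempdir(), "nope.gbk")), "no such file")
})

test_that("mRNA features are skipped by default and parsed on request", {
  gb <- c("LOCUS       MR              12 bp    DNA     linear",
          "FEATURES             Location/Qualifiers",
          "     mRNA            1..6",
          "     tRNA            7..12",
          "ORIGIN",
          "        1 acgtacacgtac",
          "//")
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gb, path)
  expect_equal(read_genbank(path)$elements$element_class, "tRNA")
  g2 <- read_genbank(path, include_mrna = TRUE)
  expect_setequal(g2$elements$element_class, c("mRNA", "tRNA"))
})

test_that("feature CSV round-trips losslessly and validates its header", {
  tab <- small_feature_table(seed = 21, n_pos = 2, n_neg = 2,
                             n_test_pos = 1, n_test_neg = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(tab, path)
  rd <- read_feature_csv(path)
  expect_identical(names(rd), names(tab)[names(tab) != "role"])
  nums <- feature_catalog()$name
  expect_equal(as.matrix(rd[, nums]), as.matrix(tab[, nums]),
               tolerance = 1e-12)
  expect_identical(rd$outcome, tab$outcome)

  bad <- utils::read.csv(path, check.names = FALSE)
  bad$mystery_column <- 1
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_feature_csv(path), "mystery_column")

  noout <- utils::read.csv(path, check.names = FALSE)
  noout$mystery_column <- NULL
  noout$outcome <- NULL
  utils::write.csv(noout, path, row.names = FALSE)
  expect_message(rd2 <- read_feature_csv(path), "unknown")
  expect_true(all(rd2$outcome == "unknown"))
})
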