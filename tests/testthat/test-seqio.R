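test_that("FASTA reading normalises and validates records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "acgt"), f)
  g <- read_fasta(f)
  expect_equal(g$id, "g1")
  expect_equal(g$seq, "ACGT")
  expect_equal(g$length_bp, 4L)

  writeLines(c(">g1", "acgu"), f)
  expect_equal(read_fasta(f)$seq, "ACGT")  # U -> T

  writeLines(c(">g1", "ACXT"), f)
  expect_error(read_fasta(f), "position 3")

  writeLines(c(">g1", "ACGT", ">g1", "ACGT"), f)
  expect_error(read_fasta(f), "g1")

  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
})

test_that("FASTA round-trips losslessly", {
  set.seed(11)
  g <- genome_set(paste0("g", 1:5),
                  replicate(5, random_dna(257)), source = "uvig")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(g, f)
  g2 <- read_fasta(f, source = "uvig")
  expect_equal(g2, g, ignore_attr = TRUE)
})

test_that("G+C content follows the report conventions", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("GGNNAT"), 0.5)  # N excluded both sides
  expect_error(gc_content("NNN"), "non-N")
  expect_equal(format_percent(0.5285), "52.85%")
  expect_equal(kb(57700), 57.7)
  set.seed(4)
  for (i in 1:20) {
    s <- random_dna(200, gc = runif(1, 0.3, 0.7))
    expect_equal(gc_content(s), gc_content(phamily:::revcomp(s)))
  }
})

test_that("GFF3 output is 1-based inclusive and round-trips", {
  ft <- feature_table("g1", 0, 3, "+", "CDS", "x")
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff(ft, f)
  ln <- readLines(f)
  expect_equal(ln[1], "##gff-version 3")
  cols <- strsplit(ln[2], "\t")[[1]]
  expect_equal(cols[4:5], c("1", "3"))

  set.seed(21)
  starts <- sort(sample(0:500, 10))
  ft10 <- feature_table(rep("g1", 10), starts, starts + sample(30:90, 10),
                        sample(c("+", "-"), 10, TRUE),
                        sample(c("CDS", "tRNA", "other"), 10, TRUE),
                        paste0("f", 1:10))
  write_gff(ft10, f)
  expect_equal(read_gff(f), ft10, ignore_attr = TRUE)

  write_gff(ft10[0, ], f)
  expect_equal(readLines(f), "##gff-version 3")  # header-only
  expect_equal(nrow(read_gff(f)), 0L)

  expect_error(write_gff(ft10, f, genome_lengths = c(g1 = 100)),
               "exceeds")
})

test_that("internal/external coordinate conversion is self-inverse", {
  s0 <- c(0L, 10L, 99L); e0 <- c(3L, 25L, 200L)
  cc <- phamily:::to_gff_coords(s0, e0)
  back <- phamily:::from_gff_coords(cc$start, cc$end)
  expect_equal(back$start, s0)
  expect_equal(back$end, e0)
  expect_equal(cc$start, s0 + 1L)
  expect_equal(cc$end, e0)
})
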