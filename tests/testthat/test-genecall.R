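island <- phamily:::STOP_ISLAND

test_that("a constructed ORF is called exactly, on both strands", {
  body <- paste0("ATG", strrep("GCT", 30), "TAA")
  set.seed(9)
  g <- genome_set("g1", paste0(random_dna(120), island, body, island,
                               random_dna(120)))
  calls <- call_orfs(g[1, ])
  hit <- calls[calls$protein == paste0("M", strrep("A", 30)), ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$end - hit$start, nchar(body))

  g2 <- genome_set("g1rc", phamily:::revcomp(g$seq))
  calls2 <- call_orfs(g2[1, ])
  hit2 <- calls2[calls2$protein == paste0("M", strrep("A", 30)), ]
  expect_equal(nrow(hit2), 1L)
  expect_equal(hit2$strand, "-")
  # coordinates mirror
  expect_equal(hit2$start, g$length_bp - hit$end)
  expect_equal(hit2$end, g$length_bp - hit$start)
})

test_that("reported proteins re-translate from reported coordinates", {
  sf <- small_family()
  g <- sf$fam$genomes[1, ]
  calls <- call_orfs(g)
  for (r in sample(nrow(calls), 10)) {
    expect_equal(translate_region(g$seq, calls$start[r], calls$end[r],
                                  calls$strand[r]),
                 calls$protein[r])
  }
})

test_that("planted genes are recovered with exact protein sequences", {
  sf <- small_family()
  recovered <- total <- 0
  for (gid in sf$fam$genomes$id) {
    planted <- sf$fam$proteomes[[gid]]
    called <- sf$calls$protein[sf$calls$genome_id == gid]
    recovered <- recovered + sum(planted %in% called)
    total <- total + length(planted)
  }
  expect_gte(recovered / total, 0.95)
})

test_that("shadow suppression keeps planted genes and drops clear shadows", {
  sf <- small_family()
  raw <- call_orfs_all(sf$fam$genomes)
  sup <- suppress_shadows(raw)
  expect_lt(nrow(sup), nrow(raw))
  for (gid in sf$fam$genomes$id) {
    planted <- sf$fam$proteomes[[gid]]
    expect_true(all(planted %in% sup$protein[sup$genome_id == gid]))
  }
})
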