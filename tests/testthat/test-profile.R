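test_that("PSSM construction matches hand-computed log-odds", {
  msa <- c(a = "MKVA", b = "MKIA", c = "MRVA", d = "MKVA", e = "MKV-")
  m <- build_profile(msa, "toy")
  expect_equal(m$length, 4L)
  bg <- phamily:::AA_BACKGROUND
  # column 2: K,K,R,K,K -> smoothed p = (count + bg) / (n + 1)
  expect_equal(unname(m$scores[2, "K"]),
               log2(((4 + bg[["K"]]) / 6) / bg[["K"]]))
  expect_equal(unname(m$scores[2, "R"]),
               log2(((1 + bg[["R"]]) / 6) / bg[["R"]]))
  # unobserved residues all score log2(1 / (n + 1))
  expect_equal(unname(m$scores[2, "W"]), log2(1 / 6))
  # column 4: one gap among five rows (<= 50%) stays a match column;
  # observed residues A,A,A,A over n = 4
  expect_equal(unname(m$scores[4, "A"]),
               log2(((4 + bg[["A"]]) / 5) / bg[["A"]]))

  # identical seeds: argmax of each column is the seed residue
  m2 <- build_profile(c(x = "MKV", y = "MKV"))
  expect_equal(colnames(m2$scores)[apply(m2$scores, 1, which.max)],
               c("M", "K", "V"))

  # fully gapped columns are dropped
  m3 <- build_profile(c(x = "A-C", y = "A-C"))
  expect_equal(m3$length, 2L)

  expect_error(build_profile(c(x = "MKV")), "single")
})

test_that("profile search passes seeds and rejects shuffles", {
  set.seed(31)
  seeds <- setNames(vapply(1:3, function(i) {
    base <- random_protein_seq(200)
    base
  }, character(1)), paste0("s", 1:3))
  # related seeds: mutate a common base
  base <- random_protein_seq(200)
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    ix <- sample(length(v), k)
    v[ix] <- sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                      "F","P","S","T","W","Y","V"), k, TRUE)
    paste(v, collapse = "")
  }
  seeds <- setNames(vapply(1:3, function(i) mut(base, 40), character(1)),
                    paste0("s", 1:3))
  msa <- center_star_msa(seeds)$rows
  model <- build_profile(msa, "toy")
  for (sd in model$seeds) {
    hits <- search_profile(model, setNames(sd, "self"))
    expect_equal(nrow(hits), 1L)
    expect_gte(hits$coverage, 0.999)
  }
  # shuffles must fail the bit-score gate
  worst <- 0
  for (i in 1:20) {
    shuf <- paste(sample(strsplit(base, "")[[1]]), collapse = "")
    h <- search_profile(model, setNames(shuf, "shuf"), bits_min = -Inf,
                        e_max = Inf, id_min = 0, cov_min = 0)
    if (nrow(h) > 0) worst <- max(worst, h$bits)
  }
  expect_lt(worst, 50)
})

test_that("the filter cascade is monotone in every threshold", {
  sf <- small_family()
  seeds <- hallmark_seed_msa(sf$fam)
  model <- build_profile(seeds$TerL, "TerL")
  prot <- sf$calls[sf$calls$genome_id %in% sf$fam$genomes$id[1:4], ]
  base <- search_profile(model, prot)
  stricter <- list(
    search_profile(model, prot, bits_min = 100),
    search_profile(model, prot, id_min = 0.6),
    search_profile(model, prot, cov_min = 0.95),
    search_profile(model, prot, e_max = 1e-30))
  for (s in stricter) {
    expect_lte(nrow(s), nrow(base))
    expect_true(all(s$orf_id %in% base$orf_id))
  }
})

test_that("hallmark retrieval separates family contigs from decoys", {
  sf <- small_family()
  seeds <- hallmark_seed_msa(sf$fam)
  models <- lapply(names(seeds), function(g) build_profile(seeds[[g]], g))
  dec <- generate_decoys(8, 12000, seed = 5)
  pool <- rbind(sf$fam$genomes, dec)
  calls <- rbind(sf$calls, call_orfs_all(dec))
  ret <- retrieve_candidates(pool, models, calls = calls)
  expect_setequal(ret$retained, sf$fam$genomes$id)
})
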