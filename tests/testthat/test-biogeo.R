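test_that("read recruitment honours the gate cascade", {
  set.seed(61)
  ref <- genome_set("r1", random_dna(8000))
  reads <- simulate_reads(ref$seq, 500, err_rate = 0, seed = 62)
  counts <- recruit_reads(reads, ref)
  expect_equal(unname(counts["r1"]), 500L)
  reads <- reads[1:100]

  # 10% substitution reads fail the identity gate
  bad <- phamily:::with_seed(63, phamily:::add_substitutions(reads, 0.10))
  expect_equal(sum(recruit_reads(bad, ref)), 0L)

  # monotone filter property
  some <- phamily:::with_seed(64, phamily:::add_substitutions(reads, 0.03))
  n_default <- sum(recruit_reads(some, ref))
  expect_lte(sum(recruit_reads(some, ref, id_min = 0.99)), n_default)
  expect_lte(sum(recruit_reads(some, ref, aln_min = 140)), n_default)
  expect_lte(sum(recruit_reads(some, ref, readcov_min = 0.99)), n_default)
  expect_error(recruit_reads(reads, ref[0, ]), "empty reference")
})

test_that("RPKM follows its defining arithmetic", {
  cm <- matrix(c(100L, 0L), 2, 1,
               dimnames = list(c("a", "b"), "s1"))
  ab <- rpkm(cm, c(a = 10000, b = 5000), totals = c(s1 = 1e6))
  expect_equal(unname(ab["a", "s1"]), 10)
  expect_equal(unname(ab["b", "s1"]), 0)
  # scale invariance
  ab2 <- rpkm(cm * 2L, c(a = 10000, b = 5000), totals = c(s1 = 2e6))
  expect_equal(unclass(ab2), unclass(ab), ignore_attr = TRUE)
  expect_warning(rpkm(matrix(0L, 1, 1, dimnames = list("a", "s")),
                      c(a = 1000)), "zero")
  expect_error(rpkm(cm, c(a = 0, b = 100)), "length")
})

test_that("environmental correlation handles perfect and degenerate rows", {
  meta <- data.frame(sample = paste0("s", 1:10), latitude = 1:10,
                     temperature = 25 - (1:10), salinity = rep(35, 10))
  ab <- rbind(lin = 2 * (1:10) + 3, flat = rep(4, 10))
  colnames(ab) <- meta$sample
  co <- env_correlate(ab, meta, vars = c("latitude", "temperature"))
  lin_lat <- co[co$genome == "lin" & co$variable == "latitude", ]
  expect_equal(lin_lat$r, 1)
  expect_lt(lin_lat$p_r, 0.05)
  expect_equal(lin_lat$slope, 2)
  expect_true(is.na(co$r[co$genome == "flat" & co$variable == "latitude"]))
  # exact permutation p at n <= 8
  meta8 <- meta[1:8, ]; ab8 <- ab[, 1:8]
  co8 <- env_correlate(ab8, meta8, vars = "latitude")
  expect_lt(co8$p_r[co8$genome == "lin"], 0.001)
})

test_that("Mann-Whitney exact p matches full enumeration", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$u, 0)
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  set.seed(71)
  for (i in 1:12) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(1:8, n1, TRUE); y <- sample(1:8, n2, TRUE)  # ties likely
    expect_equal(mann_whitney(x, y)$p, mw_oracle(x, y), tolerance = 1e-12)
  }
  # tie-free agreement with the standard test
  for (i in 1:6) {
    x <- runif(5); y <- runif(6)
    expect_equal(mann_whitney(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-9)
  }
  # identical groups sit at the null center
  expect_gte(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 0.9)
})

test_that("G+C group comparison reports the planted direction", {
  ab <- rbind(matrix(rep(30, 12), 3), matrix(rep(10, 12), 3)) +
    matrix(phamily:::with_seed(72, rnorm(24)), 6)
  rownames(ab) <- paste0("g", 1:6)
  colnames(ab) <- paste0("s", 1:4)
  gc <- setNames(c(0.38, 0.40, 0.42, 0.5, 0.55, 0.6), rownames(ab))
  res <- group_compare(ab, gc, split = 0.45)
  expect_equal(res$direction, "low>high")
  expect_equal(res$n_low, 3L)
  expect_lt(res$p, 0.2)  # exact floor for 3v3 is 0.1
  # boundary genomes join the high group
  gc2 <- gc; gc2["g3"] <- 0.45
  res2 <- group_compare(ab, gc2, split = 0.45)
  expect_equal(res2$n_high, 4L)
  expect_error(group_compare(ab, setNames(rep(0.6, 6), rownames(ab))),
               "empty")
})
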