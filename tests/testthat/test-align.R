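test_that("local and global aligners match an independent DP oracle", {
  b50 <- aa_matrix("BLOSUM50")
  al <- local_protein(c(q = "HEAGAWGHEE"), c(s = "PAWHEAE"),
                      matrix = "BLOSUM50", gap_open = 0, gap_extend = 8)
  expect_equal(al$score,
               ref_align_score("HEAGAWGHEE", "PAWHEAE", b50, 0, 8, TRUE))
  b62 <- aa_matrix()
  set.seed(101)
  for (i in 1:40) {
    q <- random_protein_seq(sample(5:60, 1))
    s <- random_protein_seq(sample(5:60, 1))
    go <- sample(c(0, 11), 1); ge <- if (go == 0) 8 else 1
    expect_equal(protein_score(q, s, gap_open = go, gap_extend = ge),
                 ref_align_score(q, s, b62, go, ge, TRUE))
    expect_equal(protein_score(q, s, gap_open = go, gap_extend = ge,
                               local = FALSE),
                 ref_align_score(q, s, b62, go, ge, FALSE))
  }
})

test_that("alignment results obey the identity and coverage contracts", {
  al <- local_protein("MKVLA", "MKVLA")
  expect_equal(al$identity, 1)
  expect_equal(al$q_cov, 1)
  expect_equal(al$s_cov, 1)
  expect_equal(global_protein("A", "G")$identity, 0)
  expect_equal(global_protein("A", "G")$aligned_cols, 1L)
  set.seed(55)
  for (i in 1:20) {
    q <- random_protein_seq(40); s <- random_protein_seq(40)
    a <- local_protein(q, s)
    # symmetry and integer match counts
    expect_equal(a$score, local_protein(s, q)$score)
    expect_equal(a$identity * a$aligned_cols, round(a$identity * a$aligned_cols))
  }
  # reversal can only lose score relative to self-alignment
  s <- random_protein_seq(50)
  r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_lte(local_protein(r, s)$score, local_protein(s, s)$score)
  expect_error(local_protein("", "MKV"), "empty")
})

test_that("nt seed-and-extend finds embedded and mutated segments", {
  set.seed(77)
  s <- random_dna(1000)
  q <- paste0(random_dna(300), s, random_dna(200))
  h <- nt_seed_extend(c(q = q), c(s = s))
  expect_gte(nrow(h), 1)
  expect_equal(h$identity[1], 1)
  expect_equal(h$s_cov[1], 1)
  expect_equal(h$qstart[1], 301)

  # 5% substitutions: top-segment identity in the binomial band
  m <- strsplit(s, "")[[1]]
  idx <- sample(1000, 50)
  m[idx] <- vapply(m[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  h2 <- nt_seed_extend(c(q = paste(m, collapse = "")), c(s = s))
  expect_gte(h2$identity[1], 0.93)
  expect_lte(h2$identity[1], 0.97)

  # disjoint alphabets: no shared k-mers
  h3 <- nt_seed_extend(c(q = strrep("AC", 50)), c(s = strrep("GT", 50)))
  expect_equal(nrow(h3), 0L)

  # reverse-strand detection
  h4 <- nt_seed_extend(c(q = phamily:::revcomp(s)), c(s = s))
  expect_equal(h4$strand[1], "-")
  expect_equal(h4$identity[1], 1)

  expect_error(nt_seed_extend(c(q = "ACGT"), c(s = s)), "k exceeds")
})

test_that("bit scores and e-values behave monotonically", {
  expect_gt(bit_score(200), bit_score(100))
  expect_lt(ka_evalue(200, 300, 300), ka_evalue(100, 300, 300))
  expect_equal(ka_evalue(100, 300, 300, 10), 10 * ka_evalue(100, 300, 300))
})
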