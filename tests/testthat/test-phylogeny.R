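test_that("center-star alignment degenerates correctly", {
  set.seed(3)
  a <- random_protein_seq(30); b <- random_protein_seq(34)
  m <- center_star_msa(c(x = a, y = b))
  al <- global_protein(c(x = a), c(y = b))
  expect_equal(length(m$rows), 2L)
  expect_equal(unique(nchar(m$rows)), m$ncol)
  expect_equal(gsub("-", "", m$rows[["x"]]), a)
  expect_equal(gsub("-", "", m$rows[["y"]]), b)
  expect_equal(m$ncol, al$aligned_cols)

  m3 <- center_star_msa(c(x = a, y = a, z = a))
  expect_false(any(grepl("-", m3$rows)))
  expect_error(center_star_msa(c(x = a)), "two")
})

test_that("trimming and concatenation keep the declared bookkeeping", {
  m1 <- structure(list(gene = "g1",
                       rows = c(a = "MK-V", b = "MKAV", c = "MKAV",
                                d = "MKAV"),
                       ncol = 4L), class = "msa")
  # column of 3 gaps among 4 rows is removed (0.75 > 0.5)
  m2 <- structure(list(gene = "g2",
                       rows = c(a = "W-CD", b = "W-CD", c = "W-CD",
                                d = "WACD"),
                       ncol = 4L), class = "msa")
  cm <- trim_and_concat(list(g1 = m1, g2 = m2), min_genes_shared = 2)
  expect_equal(cm$ncol, 4L + 3L)
  expect_equal(cm$partitions$gene, c("g1", "g2"))
  expect_equal(cm$partitions$start, c(1L, 5L))
  expect_equal(cm$partitions$end, c(4L, 7L))

  # gap-free inputs: concatenated length is the sum
  g1 <- structure(list(gene = "x", rows = c(a = "MKV", b = "MKV"),
                       ncol = 3L), class = "msa")
  g2 <- structure(list(gene = "y", rows = c(a = "WC", b = "WC"),
                       ncol = 2L), class = "msa")
  cm2 <- trim_and_concat(list(x = g1, y = g2), min_genes_shared = 2)
  expect_equal(cm2$ncol, 5L)

  # genome below min_genes_shared is excluded with a warning
  g3 <- structure(list(gene = "z", rows = c(a = "DD", b = "DD", e = "DD"),
                       ncol = 2L), class = "msa")
  expect_warning(cm3 <- trim_and_concat(list(x = g1, y = g2, z = g3),
                                        min_genes_shared = 2), "excluded")
  expect_false("e" %in% names(cm3$rows))
})

test_that("p-distance uses pairwise deletion and guards sparse overlap", {
  msa <- list(rows = c(a = strrep("MKVAW", 3), b = strrep("MKVAW", 3),
                       c = paste0(strrep("MKVAW", 2), "MAVAW")))
  D <- p_distance(msa)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 1 / 15)
  # pairwise deletion: gapped columns only drop for the affected pair
  msa3 <- list(rows = c(a = paste0("--", strrep("MKVAW", 3)),
                        b = paste0("MK", strrep("MKVAW", 3)),
                        c = paste0("MK", strrep("MKVAW", 3))))
  D3 <- p_distance(msa3)
  expect_equal(D3["a", "b"], 0)    # 15 comparable columns, all equal
  expect_equal(D3["b", "c"], 0)
  msa2 <- list(rows = c(a = "MK-----------", b = "--VAWMKVAWMKV"))
  expect_error(p_distance(msa2), "comparable columns")
})

test_that("NJ recovers additive topologies and respects path lengths", {
  # four-point example
  D <- matrix(c(0, .2, .6, .6,
                .2, 0, .6, .6,
                .6, .6, 0, .2,
                .6, .6, .2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_from_distances(D)
  expect_true(has_split(tr, c("a", "b")))
  set.seed(5)
  for (i in 1:10) {
    ra <- random_additive(sample(5:8, 1))
    tr2 <- nj_from_distances(ra$D)
    expect_equal(ape::dist.topo(ape::unroot(ra$tree), ape::unroot(tr2)), 0,
                 ignore_attr = TRUE)
    got <- ape::cophenetic.phylo(tr2)[rownames(ra$D), colnames(ra$D)]
    expect_lt(max(abs(got - ra$D)), 1e-9)
  }
})

test_that("identical sequences give a star tree with zero branch lengths", {
  msa <- list(rows = setNames(rep("MKVAWMKVAWMKVAW", 5), paste0("t", 1:5)))
  tr <- nj_tree(msa, bootstrap_n = 0)
  expect_true(all(tr$edge.length == 0))
})

test_that("bootstrap supports are reproducible under a fixed seed", {
  sf <- small_family()
  cache <- proteome_score_cache(sf$proteomes)
  core <- core_genes(ortho_groups(sf$proteomes, cache = cache),
                     names(sf$proteomes))
  msas <- list()
  for (g in core) {
    lb <- phamily:::core_label(g, sf$fam, sf$calls)
    seqs <- setNames(vapply(names(g$reps), function(gm)
      sf$proteomes[[gm]][[g$reps[[gm]]]], character(1)), names(g$reps))
    msas[[lb]] <- center_star_msa(seqs, gene = lb)
  }
  cm <- trim_and_concat(msas)
  t1 <- nj_tree(cm, bootstrap_n = 30, seed = 11)
  t2 <- nj_tree(cm, bootstrap_n = 30, seed = 11)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  # subgroups are monophyletic with strong support
  tr <- sf$fam$truth$subgroups
  for (s in unique(tr$subgroup)) {
    sup <- split_support(t1, tr$genome[tr$subgroup == s])
    expect_gte(sup, 90)
  }
})
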