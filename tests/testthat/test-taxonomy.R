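test_that("AAI handles the degenerate proteome cases", {
  set.seed(17)
  pa <- setNames(vapply(1:5, function(i) random_protein_seq(120),
                        character(1)), paste0("p", 1:5))
  self <- aai(pa, pa)
  expect_equal(self$aai, 100)
  expect_equal(self$shared_frac, 1)
  pb <- setNames(vapply(1:5, function(i) random_protein_seq(120),
                        character(1)), paste0("q", 1:5))
  none <- aai(pa, pb)
  expect_equal(none$rbh_count, 0L)
  expect_true(is.na(none$aai))
  expect_error(aai(character(0), pa), "empty")
})

test_that("AAI recovers the planted divergence on generator proteomes", {
  sf <- small_family()
  prot <- sf$fam$proteomes  # planted proteins, not gene calls
  st <- aai_matrix(prot)
  tr <- sf$fam$truth$subgroups
  same <- tr$subgroup[match(st$genome_a, tr$genome)] ==
    tr$subgroup[match(st$genome_b, tr$genome)]
  expect_true(all(abs(st$aai[same] - 75) <= 3))
  expect_true(all(st$shared_frac[same] > 0.5))
  expect_true(all(st$aai[!same] < 60 | is.na(st$aai[!same])))
})

test_that("hypergeometric network scores match exact enumeration", {
  # the fully-shared case has a closed form: P = 1 / C(10, 5)
  expect_equal(hyper_shared_p(5, 5, 5, 10), 1 / choose(10, 5))
  score <- -log10(hyper_shared_p(5, 5, 5, 10)) - log10(1)
  expect_equal(score, log10(252), tolerance = 1e-12)
  for (n in 2:12) for (a in 1:n) for (b in 1:n) {
    for (cc in 0:min(a, b)) {
      if (max(a, b) > n) next
      expect_equal(hyper_shared_p(cc, a, b, n), hyper_oracle(cc, a, b, n),
                   tolerance = 1e-12)
    }
  }
})

test_that("ortholog grouping handles identical and unrelated proteomes", {
  set.seed(19)
  pa <- setNames(vapply(1:6, function(i) random_protein_seq(150),
                        character(1)), paste0("a", 1:6))
  pb <- setNames(pa, paste0("b", 1:6))
  og <- ortho_groups(list(A = pa, B = pb))
  expect_equal(length(og), 6L)
  expect_true(all(vapply(og, function(g) nrow(g$members), integer(1)) == 2))

  pc <- setNames(vapply(1:6, function(i) random_protein_seq(150),
                        character(1)), paste0("c", 1:6))
  og2 <- ortho_groups(list(A = pa, C = pc))
  expect_equal(length(og2), 0L)
  expect_error(ortho_groups(list(A = pa)), "two genomes")
})

test_that("core genes and subgroups are recovered on the synthetic family", {
  sf <- small_family()
  cache <- proteome_score_cache(sf$proteomes)
  og <- ortho_groups(sf$proteomes, cache = cache)
  core <- core_genes(og, names(sf$proteomes))
  expect_equal(length(core), 6L)
  # every planted core gene is one family-wide group
  labs <- vapply(core, function(g) {
    lb <- phamily:::core_label(g, sf$fam, sf$calls)
    if (is.null(lb)) "?" else lb
  }, character(1))
  expect_setequal(labs, core_gene_names())
  expect_equal(length(core_genes(og, names(sf$proteomes), core_frac = 0)),
               length(og))

  st <- aai_matrix(sf$proteomes, cache = cache)
  sub <- delineate_subgroups(st)
  tr <- sf$fam$truth$subgroups
  expect_equal(phamily:::ari(sub$subgroup[match(tr$genome, sub$genome)],
                             tr$subgroup), 1)

  # input-order invariance of the subgroup labels
  st2 <- st[rev(seq_len(nrow(st))), ]
  sub2 <- delineate_subgroups(st2)
  expect_equal(sub2[order(sub2$genome), ], sub[order(sub$genome), ],
               ignore_attr = TRUE)
})

test_that("subgroup delineation degenerate gates", {
  st <- data.frame(genome_a = c("a", "a", "b"), genome_b = c("b", "c", "c"),
                   aai = 100, rbh_count = 10, shared_frac = 1)
  s1 <- delineate_subgroups(st)
  expect_equal(unique(s1$subgroup), "I")
  st$aai <- 30
  s2 <- delineate_subgroups(st)
  expect_true(all(grepl("singleton", s2$subgroup)))
})

test_that("gene-sharing network ranks subgroup pairs above cross pairs", {
  # two subgroups of three genomes sharing ONLY the six core clusters
  # across subgroups; 14 additional clusters are subgroup-specific
  genomes <- c(paste0("a", 1:3), paste0("b", 1:3))
  clusters <- list()
  proteomes <- setNames(vector("list", 6), genomes)
  add <- function(cl_name, members) clusters[[cl_name]] <<- members
  pid <- 0
  for (cl in 1:6) {                      # core: all genomes
    add(paste0("core", cl), paste0("p", pid + 1:6))
    for (g in 1:6) proteomes[[g]] <- c(proteomes[[g]],
                                       setNames("M", paste0("p", pid + g)))
    pid <- pid + 6
  }
  for (sg in c("a", "b")) for (cl in 1:14) {  # subgroup-specific
    ids <- paste0("p", pid + 1:3)
    add(paste0(sg, "spec", cl), ids)
    for (g in 1:3) {
      gn <- paste0(sg, g)
      proteomes[[gn]] <- c(proteomes[[gn]], setNames("M", ids[g]))
    }
    pid <- pid + 3
  }
  mcl_res <- list(clusters = unname(clusters), inflation = 2, iterations = 0)
  net <- gene_sharing_network(proteomes, mcl_res, min_score = 0)
  same <- substr(net$source, 1, 1) == substr(net$target, 1, 1)
  expect_true(min(net$score[same]) > max(net$score[!same]))
  # zero sharing means no edge
  expect_equal(hyper_shared_p(0, 3, 3, 34), 1)
})

test_that("proteomic distance is a bounded, truth-ordered dissimilarity", {
  set.seed(23)
  pa <- setNames(vapply(1:5, function(i) random_protein_seq(130),
                        character(1)), paste0("p", 1:5))
  expect_equal(proteomic_distance(pa, setNames(pa, paste0("x", 1:5))), 0,
               tolerance = 1e-9)
  pb <- setNames(vapply(1:5, function(i) random_protein_seq(130),
                        character(1)), paste0("q", 1:5))
  expect_equal(proteomic_distance(pa, pb), 1)

  sf <- small_family()
  dm <- distance_matrix(sf$proteomes)
  tr <- sf$fam$truth$subgroups
  grp <- tr$subgroup[match(rownames(dm), tr$genome)]
  same <- outer(grp, grp, "==")[upper.tri(dm)]
  expect_lt(max(dm[upper.tri(dm)][same]), min(dm[upper.tri(dm)][!same]))
})

test_that("subgroup-recovery ARI agrees with an established implementation", {
  set.seed(77)
  for (i in 1:10) {
    a <- sample(1:4, 30, TRUE); b <- sample(1:4, 30, TRUE)
    expect_equal(phamily:::ari(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(phamily:::ari(1:10, 1:10), 1)
})
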