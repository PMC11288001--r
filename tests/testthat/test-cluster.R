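test_that("length-proxy completeness applies the strict drop rule", {
  g <- genome_set(c("full", "half", "frag"),
                  c(strrep("ACGT", 250), strrep("ACGT", 125),
                    strrep("ACGT", 75)))
  cf <- completeness_filter(g, expected_len = 1000)
  expect_setequal(cf$retained$id, c("full", "half"))  # 0.5 is kept
  expect_equal(cf$report$completeness, c(1, 0.5, 0.3))
  expect_error(completeness_filter(g, "auto"), "trusted")
  cf2 <- completeness_filter(g, "auto", trusted = "full")
  expect_true("half" %in% cf2$retained$id)
})

test_that("greedy dereplication follows the CD-HIT conventions", {
  set.seed(41)
  a <- random_dna(2000)
  dup <- greedy_derep(setNames(c(a, a), c("a", "b")))
  expect_equal(dup$centroids, "a")
  expect_equal(dup$map$centroid, c("a", "a"))

  # ~90% identity: below the 0.95 gate
  v <- strsplit(a, "")[[1]]
  ix <- sample(2000, 200)
  v[ix] <- vapply(v[ix], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  two <- greedy_derep(setNames(c(a, paste(v, collapse = "")), c("a", "b")))
  expect_equal(sort(two$centroids), c("a", "b"))

  # ten 2%-mutated copies collapse to one centroid
  copies <- phamily:::with_seed(99, phamily:::add_substitutions(rep(a, 10), 0.02))
  dr <- greedy_derep(setNames(c(a, copies), c("ref", paste0("c", 1:10))))
  expect_equal(length(dr$centroids), 1L)

  # idempotence on centroids
  again <- greedy_derep(setNames(a, "ref"))
  expect_equal(again$centroids, "ref")
})

test_that("markov clustering recovers planted graph structure", {
  cl4 <- function(p) t(combn(paste0(p, 1:4), 2))
  edges <- rbind(data.frame(from = cl4("a")[, 1], to = cl4("a")[, 2], w = 1),
                 data.frame(from = cl4("b")[, 1], to = cl4("b")[, 2], w = 1))
  r <- mcl(edges)
  expect_equal(length(r$clusters), 2L)
  expect_setequal(vapply(r$clusters, function(x)
    paste(sort(x), collapse = ","), character(1)),
    c("a1,a2,a3,a4", "b1,b2,b3,b4"))

  r2 <- mcl(data.frame(from = "A", to = "B", w = 1))
  expect_equal(length(r2$clusters), 1L)
  expect_setequal(r2$clusters[[1]], c("A", "B"))

  # barbell: two 5-cliques joined by one weak edge
  cl5 <- function(p) t(combn(paste0(p, 1:5), 2))
  bb <- rbind(data.frame(from = cl5("x")[, 1], to = cl5("x")[, 2], w = 1),
              data.frame(from = cl5("y")[, 1], to = cl5("y")[, 2], w = 1),
              data.frame(from = "x1", to = "y1", w = 0.01))
  rb <- mcl(bb)
  expect_equal(length(rb$clusters), 2L)

  # relabel invariance (up to permutation)
  perm <- setNames(paste0("n", sample(10)), c(paste0("x", 1:5), paste0("y", 1:5)))
  bb2 <- data.frame(from = perm[bb$from], to = perm[bb$to], w = bb$w)
  rb2 <- mcl(bb2)
  canon <- function(res, map = identity)
    sort(vapply(res$clusters, function(x)
      paste(sort(map(x)), collapse = ","), character(1)))
  expect_equal(canon(rb, function(x) unname(perm[x])), canon(rb2))

  expect_equal(mcl(NULL)$clusters, list())
})

test_that("derep centroid count is monotone in the identity gate", {
  set.seed(63)
  a <- random_dna(1500)
  seqs <- c(a, phamily:::with_seed(1, phamily:::add_substitutions(rep(a, 4), 0.04)))
  names(seqs) <- paste0("g", 1:5)
  n95 <- length(greedy_derep(seqs, id_min = 0.95)$centroids)
  n90 <- length(greedy_derep(seqs, id_min = 0.90)$centroids)
  expect_lte(n90, n95)
})
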