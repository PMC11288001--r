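# Independent oracles used across the suite.

# Plain-R affine-gap DP (score only), written independently of the
# package's C++ aligner: three-state recursion with explicit loops.
# Gap model: gap of length L costs gap_open + L * gap_extend.
ref_align_score <- function(q, s, sm, gap_open, gap_extend, local) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  NEG <- -1e30
  H <- matrix(NEG, n + 1, m + 1); E <- H; F <- H
  H[1, 1] <- 0
  for (j in 2:(m + 1)) {
    E[1, j] <- -(gap_open + (j - 1) * gap_extend)
    H[1, j] <- if (local) 0 else E[1, j]
  }
  for (i in 2:(n + 1)) {
    F[i, 1] <- -(gap_open + (i - 1) * gap_extend)
    H[i, 1] <- if (local) 0 else F[i, 1]
  }
  best <- if (local) 0 else NEG
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      d <- H[i - 1, j - 1] + sm[qc[i - 1], sc[j - 1]]
      h <- max(d, E[i, j], F[i, j])
      if (local) h <- max(h, 0)
      H[i, j] <- h
      if (local && h > best) best <- h
    }
  }
  if (local) best else H[n + 1, m + 1]
}

random_protein_seq <- function(len) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                 "F","P","S","T","W","Y","V"), len, replace = TRUE),
        collapse = "")
}

random_dna <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Exact hypergeometric sharing probability by direct summation of the
# combinatorial terms (independent of phyper).
hyper_oracle <- function(c_shared, a, b, n) {
  if (c_shared == 0) return(1)
  i <- c_shared:min(a, b)
  sum(choose(a, i) * choose(n - a, b - i)) / choose(n, b)
}

# Exact two-sided Mann-Whitney p by enumerating group assignments of the
# observed VALUES (handles ties naturally).
mw_oracle <- function(x, y) {
  n1 <- length(x); vals <- c(x, y)
  combs <- combn(length(vals), n1)
  u_of <- function(ix) {
    xx <- vals[ix]; yy <- vals[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  us <- apply(combs, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# Random additive distance matrix from a random tree with its generating
# topology, for NJ recovery checks.
random_additive <- function(n) {
  tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# small synthetic family shared by several module tests
small_family <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      fs <- family_spec(n_subgroups = 3, genomes_per_subgroup = 3,
                        ancestor_gene_count = 15, genome_len_bp = 15000,
                        seed = 7)
      fam <- generate_family(fs)
      calls <- suppress_shadows(call_orfs_all(fam$genomes))
      memo <<- list(fam = fam, calls = calls,
                    proteomes = proteomes_from_calls(calls))
    }
    memo
  }
})
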