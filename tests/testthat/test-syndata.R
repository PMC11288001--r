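test_that("generation is byte-identical under a fixed seed", {
  fs <- family_spec(n_subgroups = 2, genomes_per_subgroup = 2,
                    ancestor_gene_count = 10, genome_len_bp = 10000,
                    seed = 33)
  f1 <- generate_family(fs)
  f2 <- generate_family(fs)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_fasta(f1$genomes, p1); write_fasta(f2$genomes, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(f1$truth, f2$truth)
})

test_that("a single undiverged genome carries all six core genes", {
  fs <- family_spec(n_subgroups = 1, genomes_per_subgroup = 1,
                    ancestor_gene_count = 10, genome_len_bp = 10000,
                    within_divergence = 1, between_divergence = 0.35,
                    seed = 2)
  fam <- generate_family(fs)
  expect_equal(nrow(fam$genomes), 1L)
  core <- fam$truth$core
  expect_setequal(core$label, core_gene_names())
})

test_that("realized divergence and G+C hit the spec windows", {
  sf <- small_family()
  fam <- sf$fam
  # measure amino-acid identity with the pairwise aligner on core genes
  tr <- fam$truth$subgroups
  pick <- function(gid, gene) fam$proteomes[[gid]][[paste0(gid, "_", gene)]]
  within <- between <- c()
  for (gene in core_gene_names()) {
    within <- c(within, global_protein(pick("sg1_g1", gene),
                                       pick("sg1_g2", gene))$identity)
    between <- c(between, global_protein(pick("sg1_g1", gene),
                                         pick("sg2_g1", gene))$identity)
  }
  expect_gte(mean(within), 0.70); expect_lte(mean(within), 0.80)
  expect_gte(mean(between), 0.30); expect_lte(mean(between), 0.40)
  gc <- gc_content(fam$genomes)
  expect_true(all(abs(gc - tr$gc_target) <= 0.03))
})

test_that("lysogen construction conserves sequence and plants the core once", {
  fs <- family_spec(n_subgroups = 1, genomes_per_subgroup = 1,
                    ancestor_gene_count = 10, genome_len_bp = 12000,
                    integrase_prob = 1, seed = 8)
  fam <- generate_family(fs)
  phage <- fam$genomes[1, ]
  ptr <- fam$features[fam$features$kind == "tRNA", ]
  h <- generate_host(30000, seed = 9)
  lys <- generate_lysogen(phage, h$genome, h$features, phage_trnas = ptr,
                          att_len = 13, seed = 10)
  expect_equal(lys$lysogen$length_bp,
               h$genome$length_bp + phage$length_bp)
  core <- lys$truth$core
  expect_equal(nchar(core), 13L)
  # attL / attR flanks each contain the core exactly once
  ls <- lys$lysogen$seq
  attL <- substr(ls, lys$truth$attL["start"] - 200, lys$truth$attL["end"] + 200)
  attR <- substr(ls, lys$truth$attR["start"] - 200, lys$truth$attR["end"] + 200)
  cnt <- function(x) sum(gregexpr(core, x, fixed = TRUE)[[1]] > 0)
  expect_equal(cnt(attL), 1L)
  expect_equal(cnt(attR), 1L)
  # determinism
  lys2 <- generate_lysogen(phage, h$genome, h$features, phage_trnas = ptr,
                           att_len = 13, seed = 10)
  expect_identical(lys$lysogen$seq, lys2$lysogen$seq)
  expect_error(generate_lysogen(phage, h$genome, h$features, att_len = 5),
               "att_len")
})

test_that("virome simulation has the stated error and abundance structure", {
  g <- genome_set("g1", random_dna(5000))
  vir <- simulate_viromes(g, n_samples = 3, reads_per_sample = 200,
                          err_rate = 0, seed = 12)
  for (rd in vir$reads$s01) {
    expect_true(grepl(rd, g$seq, fixed = TRUE) ||
                  grepl(phamily:::revcomp(rd), g$seq, fixed = TRUE))
  }
  expect_error(simulate_viromes(g, n_samples = 2), "3 samples")

  # null model: equal planted abundances
  g2 <- genome_set(c("a", "b"), c(random_dna(5000), random_dna(5000)))
  vir0 <- simulate_viromes(g2, n_samples = 6,
                           model = virome_model(beta = c(a = 0, b = 0),
                                                noise_sd = 0),
                           reads_per_sample = 500, seed = 13)
  expect_true(all(abs(vir0$truth$rel_abundance - 0.5) < 1e-9))

  # beta = +/-1: Spearman sign of the planted abundances matches beta
  vir1 <- simulate_viromes(g2, n_samples = 12,
                           model = virome_model(beta = c(a = 1, b = -1)),
                           reads_per_sample = 500, seed = 14)
  tt <- vir1$truth
  lat <- vir1$meta$latitude[match(tt$sample, vir1$meta$sample)]
  for (gn in c("a", "b")) {
    rho <- cor(lat[tt$genome == gn], tt$rel_abundance[tt$genome == gn],
               method = "spearman")
    expect_equal(sign(rho), unname(c(a = 1, b = -1)[gn]))
  }
})

test_that("FASTQ output round-trips reads at constant Q30", {
  reads <- c("ACGT", "GGCC")
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  ln <- readLines(f)
  expect_equal(length(ln), 8L)
  expect_equal(ln[4], "????")
  expect_equal(read_fastq(f), reads)
})
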