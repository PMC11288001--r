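make_lysogen <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      fs <- family_spec(n_subgroups = 1, genomes_per_subgroup = 1,
                        ancestor_gene_count = 12, genome_len_bp = 14000,
                        integrase_prob = 1, seed = 3)
      fam <- generate_family(fs)
      phage <- fam$genomes[1, ]
      ptr <- fam$features[fam$features$kind == "tRNA", ]
      h <- generate_host(30000, seed = 4)
      lys <- generate_lysogen(phage, h$genome, h$features, phage_trnas = ptr,
                              att_len = 13, seed = 5)
      memo <<- list(fam = fam, phage = phage, ptr = ptr, lys = lys)
    }
    memo
  }
})

test_that("the planted att core is found rank-1 at exact coordinates", {
  L <- make_lysogen()
  att <- find_att(L$lys$phage, L$lys$host, host_trnas = L$lys$host_features,
                  phage_trnas = L$ptr)
  expect_gt(nrow(att), 0)
  expect_equal(att$core[1], L$lys$truth$core)
  expect_equal(att$phage_start[1], unname(L$lys$truth$attP["start"]))
  expect_equal(att$host_start[1], unname(L$lys$truth$attB["start"]))
  expect_true(att$overlaps_host_tRNA[1])
  expect_true(att$near_phage_tRNA[1])
  # Campbell arithmetic for the integrated map
  expect_equal(att$attL_start[1], unname(L$lys$truth$attL["start"]))
  expect_equal(att$attR_start[1], unname(L$lys$truth$attR["start"]))
  # reported cores re-verify by substring equality at both loci
  for (r in seq_len(min(nrow(att), 5))) {
    pc <- substr(L$lys$phage$seq, att$phage_start[r] + 1, att$phage_end[r])
    hc <- substr(L$lys$host$seq, att$host_start[r] + 1, att$host_end[r])
    if (att$strand[r] == "-") hc <- phamily:::revcomp(hc)
    expect_equal(pc, att$core[r])
    expect_equal(hc, att$core[r])
  }
  expect_error(find_att(L$lys$phage, L$lys$host, min_len = 7), "noise floor")
})

test_that("att search is empty without shared material and symmetric", {
  a <- genome_set("a", strrep("A", 80))
  b <- genome_set("b", strrep("C", 80))
  expect_equal(nrow(find_att(a[1, ], b[1, ], min_len = 8)), 0L)
  L <- make_lysogen()
  fw <- find_att(L$lys$phage, L$lys$host)
  bw <- find_att(L$lys$host, L$lys$phage)
  # same sites with roles exchanged (reverse-strand cores are reported
  # in the query orientation)
  canon <- function(x) pmin(x, phamily:::revcomp(x))
  expect_setequal(canon(fw$core), canon(bw$core))
  expect_setequal(paste(fw$phage_start, fw$host_start),
                  paste(bw$host_start, bw$phage_start))
})

test_that("a reverse-strand core is found and flagged", {
  set.seed(31)
  core <- random_dna(14)
  a <- genome_set("a", paste0(random_dna(400), core, random_dna(400)))
  b <- genome_set("b", paste0(random_dna(300), phamily:::revcomp(core),
                              random_dna(500)))
  att <- find_att(a[1, ], b[1, ])
  expect_gt(nrow(att), 0)
  expect_equal(att$strand[1], "-")
  expect_equal(att$core[1], core)
})

test_that("junction detection pins attL/attR from lysogen reads", {
  L <- make_lysogen()
  reads <- simulate_reads(L$lys$lysogen$seq, 6000, seed = 6)
  jx <- junction_detect(reads, L$lys$phage, L$lys$host)
  expect_equal(nrow(jx), 2L)
  expect_setequal(jx$side, c("left", "right"))
  attP <- L$lys$truth$attP
  expect_lte(abs(jx$phage_pos[jx$side == "left"] - (attP["start"] + 1)), 1)
  expect_lte(abs(jx$phage_pos[jx$side == "right"] - attP["end"]), 1)

  # pure phage reads yield no junctions
  pure <- simulate_reads(L$lys$phage$seq, 500, seed = 7)
  expect_equal(nrow(junction_detect(pure, L$lys$phage, L$lys$host)), 0L)
  expect_error(junction_detect(pure, L$lys$phage, L$lys$host, clip_min = 80),
               "clip_min")
})

test_that("prophage calls bound the planted integration", {
  L <- make_lysogen()
  pro <- find_prophage(L$lys$phage, L$lys$lysogen)
  expect_equal(nrow(pro), 1L)
  expect_lte(abs(pro$start - L$lys$truth$attL[["start"]]), 200)
  expect_lte(abs(pro$end - L$lys$truth$attR[["end"]]), 200)
  expect_gte(pro$ref_coverage, 0.5)
  expect_gte(pro$mean_identity, 0.95)

  # a contig without prophage
  clean <- genome_set("c", phamily:::with_seed(8, paste(
    sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")))
  expect_equal(nrow(find_prophage(L$lys$phage, clean)), 0L)

  # a 90% identity relative stays below the gates
  mut <- phamily:::with_seed(9, phamily:::add_substitutions(
    L$lys$lysogen$seq, 0.10))
  far <- genome_set("far", mut)
  expect_equal(nrow(find_prophage(L$lys$phage, far)), 0L)
})
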