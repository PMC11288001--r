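# syndata: synthetic phage family, hosts, lysogens and virome read sets
# with complete planted truth.  Divergence is star-within-star: a family
# ancestor proteome, per-subgroup ancestors, then per-genome leaves,
# with per-site amino-acid substitution rates calibrated in closed form
# so realized pairwise identities hit the requested within/between
# targets.  Nucleotide sequences are back-translated with synonymous
# codon choice weighted to hit per-subgroup G+C targets; "stop island"
# spacers flank every gene so the ORF caller recovers planted proteins
# exactly.

STOP_ISLAND <- "TTAATTAATTAATTAA"  # stops in all six frames, self-revcomp

#' Specification of a synthetic phage family
#'
#' @param n_subgroups,genomes_per_subgroup family shape.
#' @param ancestor_gene_count genes in the family ancestor (default 63).
#' @param genome_len_bp target genome length (default 57,700).
#' @param within_divergence target mean pairwise amino-acid identity
#'   within a subgroup (default 0.75).
#' @param between_divergence target identity between subgroups
#'   (default 0.35).  Must be below `within_divergence`.
#' @param gc_targets per-subgroup G+C fractions in `[0.35, 0.66]`
#'   (default: evenly spaced over `[0.38, 0.62]`).
#' @param integrase_prob probability a genome carries the family
#'   integrase gene (default 0.85).
#' @param seed integer seed; the same spec + seed is byte-identical.
#' @return a `family_spec` list.
#' @export
family_spec <- function(n_subgroups = 3, genomes_per_subgroup = 5,
                        ancestor_gene_count = 63, genome_len_bp = 57700,
                        within_divergence = 0.75, between_divergence = 0.35,
                        gc_targets = NULL, integrase_prob = 0.85, seed = 1) {
  if (is.null(gc_targets))
    gc_targets <- if (n_subgroups == 1) 0.5 else
      seq(0.38, 0.62, length.out = n_subgroups)
  stopifnot(n_subgroups >= 1, genomes_per_subgroup >= 1,
            within_divergence > between_divergence || within_divergence == 1,
            length(gc_targets) == n_subgroups)
  if (any(gc_targets < 0.35 | gc_targets > 0.66))
    stop("gc_targets outside the supported range [0.35, 0.66]")
  structure(list(n_subgroups = n_subgroups,
                 genomes_per_subgroup = genomes_per_subgroup,
                 ancestor_gene_count = ancestor_gene_count,
                 genome_len_bp = genome_len_bp,
                 within_divergence = within_divergence,
                 between_divergence = between_divergence,
                 gc_targets = gc_targets, integrase_prob = integrase_prob,
                 seed = seed), class = "family_spec")
}

# closed-form per-branch substitution probabilities for the star-within-
# star model.  Mutated sites redraw from the background (possibly the
# same residue); with c = sum(bg^2) the chance two independently
# redrawn sites agree, E[identity] = A + (1 - A) c where A is the
# probability neither lineage mutated a site.
divergence_rates <- function(within, between) {
  cc <- sum(AA_BACKGROUND^2)
  if (within >= 1) return(list(u = 0, v = 1 - sqrt(max(0, (between - cc) / (1 - cc)))))
  if (between <= cc) stop("between_divergence at or below chance identity")
  Aw <- (within - cc) / (1 - cc)
  Ab <- (between - cc) / (1 - cc)
  list(u = 1 - sqrt(Aw), v = 1 - sqrt(Ab / Aw))
}

# Refine the closed-form rates against the package's own pairwise
# aligner: realized identity is measured as optimal LOCAL alignment
# identity (the AAI estimator), which sits slightly above the per-site
# identity at high divergence because the optimal alignment is free to
# trim and realign.  Two secant steps per rate on the full ancestor
# proteome bring the realized local identity onto the target.
calibrate_rates <- function(ancestor, within, between, rates) {
  genes <- ancestor[vapply(ancestor, nchar, integer(1)) >= 80]
  measure <- function(u, v) {
    ids <- vapply(genes, function(g) {
      gc <- chars(g)
      a <- paste(mutate_protein(mutate_protein(gc, v), u), collapse = "")
      b <- paste(mutate_protein(mutate_protein(gc, v), u), collapse = "")
      al <- cpp_pair_align(aa_encode(a), aa_encode(b), aa_matrix(), 11, 1, TRUE)
      if (al$aligned_cols > 0) al$matches / al$aligned_cols else 0
    }, numeric(1))
    mean(ids)
  }
  cc <- sum(AA_BACKGROUND^2)
  clamp_t <- function(t) min(0.995, max(cc + 0.01, t))
  u_of <- function(t) 1 - sqrt((clamp_t(t) - cc) / (1 - cc))
  v_of <- function(t, u) {
    a <- sqrt((clamp_t(t) - cc) / (1 - cc)) / (1 - u)
    1 - min(1, max(0, a))
  }
  # measure the local-alignment bias at the model rates, shift the
  # model target by the residual, and re-solve the closed form
  if (within < 1) {
    t <- within
    for (it in 1:2) {
      resid <- measure(rates$u, 0) - within
      t <- clamp_t(t - resid)
      rates$u <- u_of(t)
    }
  }
  t <- between
  for (it in 1:2) {
    resid <- measure(rates$u, rates$v) - between
    t <- clamp_t(t - resid)
    rates$v <- v_of(t, rates$u)
  }
  rates
}

mutate_protein <- function(aa_chars, rate) {
  if (rate <= 0) return(aa_chars)
  hit <- runif(length(aa_chars)) < rate
  hit[1] <- FALSE  # initiator M is invariant
  n <- sum(hit)
  if (n > 0)
    aa_chars[hit] <- sample(names(AA_BACKGROUND), n, replace = TRUE,
                            prob = AA_BACKGROUND)
  aa_chars
}

random_protein <- function(len) {
  paste(c("M", sample(names(AA_BACKGROUND), len - 1, replace = TRUE,
                      prob = AA_BACKGROUND)), collapse = "")
}

# ---- codon machinery for G+C controlled back-translation ---------------

codons_by_aa <- function() {
  if (is.null(.align_env$cod_by_aa)) {
    tab <- codon_table()
    cods <- names(tab)[tab != "*"]
    .align_env$cod_by_aa <- split(cods, unname(tab[cods]))
    .align_env$cod_gc <- vapply(cods, function(cd)
      sum(chars(cd) %in% c("G", "C")), numeric(1))
  }
  .align_env$cod_by_aa
}

# expected coding G+C fraction under weights w(codon) ~ exp(gamma * gc)
expected_coding_gc <- function(aa_freq, gamma) {
  by_aa <- codons_by_aa()
  gcv <- .align_env$cod_gc
  num <- den <- 0
  for (a in names(aa_freq)) {
    cods <- by_aa[[a]]
    w <- exp(gamma * gcv[cods])
    num <- num + aa_freq[[a]] * sum(w * gcv[cods]) / sum(w)
    den <- den + aa_freq[[a]] * 3
  }
  num / den
}

# back-translate one protein; returns the coding sequence incl. TAA stop
back_translate <- function(protein, gamma) {
  by_aa <- codons_by_aa()
  gcv <- .align_env$cod_gc
  aas <- chars(protein)
  out <- character(length(aas))
  for (a in unique(aas)) {
    cods <- by_aa[[a]]
    w <- exp(gamma * gcv[cods])
    idx <- which(aas == a)
    out[idx] <- if (length(cods) == 1) cods else
      sample(cods, length(idx), replace = TRUE, prob = w / sum(w))
  }
  out[1] <- "ATG"  # initiator
  paste(c(out, "TAA"), collapse = "")
}

solve_gamma <- function(proteins, gc_target) {
  aa_freq <- table(factor(chars(paste(proteins, collapse = "")),
                          levels = names(AA_BACKGROUND)))
  aa_freq <- aa_freq / sum(aa_freq)
  f <- function(g) expected_coding_gc(aa_freq, g) - gc_target
  lo <- f(-6); hi <- f(6)
  if (lo > 0 || hi < 0)
    stop("G+C target ", gc_target, " infeasible for this proteome; ",
         "relax gc_targets")
  stats::uniroot(f, c(-6, 6), tol = 1e-6)$root
}

# a compact synthetic tRNA-like gene (acceptor stem + anticodon region)
random_trna <- function(len = 72) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c(0.22, 0.28, 0.28, 0.22)), collapse = "")
}

# ---- family generation -------------------------------------------------

#' Generate a synthetic phage family with planted truth
#'
#' See [family_spec()] for the model.  Each genome carries the six core
#' genes (portal, TerL, capsid, PD-(D/E)XK nuclease, AAA ATPase,
#' Prim-Pol), subgroup-variable accessory genes (some lost per subgroup,
#' some subgroup-exclusive), optionally the family integrase, and one
#' tRNA locus.  Genes are flanked by stop islands and separated by
#' composition-matched spacers.
#'
#' @param spec a [family_spec()].
#' @return list: `genomes` (genome table), `proteomes` (named list of
#'   named protein vectors), `features` (CDS + tRNA feature table,
#'   0-based half-open), `truth` (list: `subgroups` data.frame,
#'   `pair_identity` data.frame of planted target mean identities,
#'   `core` data.frame of core-gene coordinates, `spec` echo).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    ns <- spec$n_subgroups; gps <- spec$genomes_per_subgroup
    ng <- spec$ancestor_gene_count
    if (ng < 7) stop("need at least 7 ancestor genes (6 core + accessory)")
    rates <- divergence_rates(spec$within_divergence, spec$between_divergence)
    island <- STOP_ISLAND
    # gene lengths sized so genes + islands + spacers fill the genome
    # gene-length budget targets ~92% coding density (phage-like) for
    # the EXPECTED realized gene count: ~15% of accessories are lost per
    # genome while the integrase and subgroup-exclusive genes are gained
    mean_nt <- spec$genome_len_bp * 0.92 / (ng * 0.85 + 4)
    mean_aa <- max(80, floor((mean_nt - 2 * nchar(island) - 40) / 3) - 1)
    aa_len <- pmax(60, round(rgamma(ng, shape = 6, rate = 6 / mean_aa)))
    core_idx <- round(seq(2, ng - 1, length.out = 6))
    gene_names <- paste0("acc", seq_len(ng))
    gene_names[core_idx] <- core_gene_names()
    # hallmark/core genes (portal, TerL, capsid ...) are substantial
    # proteins; keep them at least average-sized
    aa_len[core_idx] <- pmax(aa_len[core_idx], round(mean_aa), 150)
    ancestor <- lapply(aa_len, random_protein)
    names(ancestor) <- gene_names
    rates <- calibrate_rates(ancestor, spec$within_divergence,
                             spec$between_divergence, rates)
    integrase <- random_protein(max(200, mean_aa))
    trna <- random_trna()
    acc_names <- setdiff(gene_names, core_gene_names())
    genomes <- list(); proteomes <- list(); feats <- list()
    truth_sub <- list(); truth_core <- list()
    # per-subgroup gene sets (accessory turnover: lose ~8%, gain 3
    # exclusive genes), then per-genome presence with sporadic accessory
    # loss; every non-core gene is forced absent from at least one
    # genome so the family-wide core is exactly the planted six
    sg_gene_sets <- list(); sg_ancs <- list()
    for (sg in seq_len(ns)) {
      sg_ancs[[sg]] <- lapply(ancestor, function(p)
        mutate_protein(chars(p), rates$v))
      lost <- sample(acc_names, max(0, round(0.08 * length(acc_names))))
      gained <- setNames(lapply(1:3, function(k)
        chars(random_protein(max(60, round(mean_aa * 0.8))))),
        paste0("sgx", sg, "_", 1:3))
      sg_ancs[[sg]] <- c(sg_ancs[[sg]], gained)
      sg_gene_sets[[sg]] <- c(setdiff(gene_names, lost), names(gained))
    }
    gids <- as.vector(t(outer(seq_len(ns), seq_len(gps),
                              function(a, b) sprintf("sg%d_g%d", a, b))))
    presence <- list()
    for (sg in seq_len(ns)) for (gi in seq_len(gps)) {
      gid <- sprintf("sg%d_g%d", sg, gi)
      gset <- sg_gene_sets[[sg]]
      accs <- setdiff(gset, core_gene_names())
      drop_g <- accs[runif(length(accs)) < 0.08]
      presence[[gid]] <- setdiff(gset, drop_g)
    }
    has_int <- setNames(runif(length(gids)) < spec$integrase_prob, gids)
    if (length(gids) >= 2) {
      all_genes <- unique(unlist(presence))
      for (g in setdiff(all_genes, core_gene_names())) {
        carriers <- gids[vapply(presence[gids], function(p) g %in% p,
                                logical(1))]
        if (length(carriers) == length(gids)) {
          victim <- sample(carriers, 1)
          presence[[victim]] <- setdiff(presence[[victim]], g)
        }
      }
      if (all(has_int) && spec$integrase_prob < 1)
        has_int[sample(gids, 1)] <- FALSE
    }
    for (sg in seq_len(ns)) {
      gc_t <- spec$gc_targets[sg]
      for (gi in seq_len(gps)) {
        gid <- sprintf("sg%d_g%d", sg, gi)
        sg_genes <- sg_ancs[[sg]][presence[[gid]]]
        prots <- lapply(sg_genes, mutate_protein, rate = rates$u)
        prots <- lapply(prots, paste, collapse = "")
        if (has_int[gid]) prots$integrase <- paste(
          mutate_protein(chars(integrase), rates$u), collapse = "")
        res <- assemble_genome(gid, prots, gc_t, trna,
                               spec$genome_len_bp, island)
        genomes[[gid]] <- res$seq
        proteomes[[gid]] <- res$proteins
        feats[[gid]] <- res$features
        truth_sub[[gid]] <- data.frame(genome = gid, subgroup = sg,
                                       gc_target = gc_t,
                                       has_integrase = unname(has_int[gid]),
                                       stringsAsFactors = FALSE)
        tc <- res$features[res$features$label %in% core_gene_names(), ]
        truth_core[[gid]] <- tc
      }
    }
    gdf <- genome_set(names(genomes), unlist(genomes), source = "synthetic")
    subs <- do.call(rbind, truth_sub)
    pid <- expand_pair_identity(subs, spec)
    list(genomes = gdf, proteomes = proteomes,
         features = do.call(rbind, c(feats, list(make.row.names = FALSE))),
         truth = list(subgroups = subs, pair_identity = pid,
                      core = do.call(rbind, c(truth_core,
                                              list(make.row.names = FALSE))),
                      spec = spec))
  })
}

# lay out genes (random strand) with stop islands and G+C matched spacers.
# The synonymous-codon bias gamma is solved per genome so that coding +
# stop islands + spacers + tRNA jointly hit the genome-wide G+C target.
assemble_genome <- function(gid, prots, gc_target, trna,
                            target_len, island) {
  n <- length(prots)
  coding_nt <- sum(3 * (nchar(unlist(prots)) + 1))
  island_nt <- 2 * n * nchar(island)
  trna_nt <- nchar(trna)
  n_gaps <- n + 2L  # before first gene, between genes, after last (tRNA slot)
  spacer_len <- rep(30L, n_gaps)
  extra <- target_len - coding_nt - island_nt - trna_nt - sum(spacer_len)
  if (extra > 0) spacer_len <- spacer_len + c(rep(extra %/% n_gaps, n_gaps - 1),
                                              extra %/% n_gaps + extra %% n_gaps)
  # long spacers are interleaved with stop islands (one per 64 bp) so no
  # spurious ORF of >= 30 codons can arise intergenically
  isl_per_spacer <- spacer_len %/% 64L
  spacer_rand <- spacer_len - 16L * isl_per_spacer
  island_nt <- island_nt + 16L * sum(isl_per_spacer)
  total_len <- coding_nt + island_nt + trna_nt + sum(spacer_rand)
  trna_gc <- nchar(gsub("[AT]", "", trna))
  # aim coding at the genome target after discounting spacers at the
  # same composition, then clamp to what synonymous choice can reach
  # and let the spacers absorb the residual (AT-only stop islands
  # always pull the genome down)
  coding_target <- (gc_target * total_len - gc_target * sum(spacer_rand) -
                      trna_gc) / coding_nt
  aa_freq <- table(factor(chars(paste(unlist(prots), collapse = "")),
                          levels = names(AA_BACKGROUND)))
  aa_freq <- aa_freq / sum(aa_freq)
  lo <- expected_coding_gc(aa_freq, -6) + 0.005
  hi <- expected_coding_gc(aa_freq, 6) - 0.005
  coding_target <- min(max(coding_target, lo), hi)
  p_gc <- (gc_target * total_len - coding_target * coding_nt - trna_gc) /
    sum(spacer_rand)
  if (p_gc < 0.02 || p_gc > 0.98)
    stop("G+C target ", gc_target, " infeasible for this gene density; ",
         "relax gc_targets")
  gamma <- solve_gamma(unlist(prots), coding_target)
  nt <- lapply(prots, back_translate, gamma = gamma)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  draw_rand <- function(L) if (L == 0) "" else paste(sample(
    c("A", "C", "G", "T"), L, replace = TRUE,
    prob = c((1 - p_gc) / 2, p_gc / 2, p_gc / 2, (1 - p_gc) / 2)),
    collapse = "")
  draw_spacer <- function(L) {
    n_isl <- L %/% 64L
    if (n_isl == 0) return(draw_rand(L))
    rand_each <- (L - 16L * n_isl) %/% (n_isl + 1L)
    rem <- (L - 16L * n_isl) %% (n_isl + 1L)
    parts <- character(2 * n_isl + 1)
    for (u in seq_len(n_isl)) {
      parts[2 * u - 1] <- draw_rand(rand_each)
      parts[2 * u] <- island
    }
    parts[2 * n_isl + 1] <- draw_rand(rand_each + rem)
    paste(parts, collapse = "")
  }
  parts <- character(0); pos <- 0L
  feats <- list(); prot_out <- character(0)
  add <- function(s) { parts[[length(parts) + 1L]] <<- s; pos <<- pos + nchar(s) }
  trna_after <- as.integer(ceiling(n / 2))  # tRNA locus is interior
  add(draw_spacer(spacer_len[1]))
  for (k in seq_len(n)) {
    gene <- names(nt)[k]
    add(island)
    gstart <- pos
    body <- if (strand[k] == "+") nt[[k]] else revcomp(nt[[k]])
    add(body)
    feats[[length(feats) + 1L]] <- data.frame(
      genome_id = gid, start = gstart, end = pos, strand = strand[k],
      kind = "CDS", label = gene, stringsAsFactors = FALSE)
    prot_out[paste0(gid, "_", gene)] <- prots[[gene]]
    add(island)
    add(draw_spacer(spacer_len[k + 1]))
    if (k == trna_after) {
      tstart <- pos
      add(trna)
      feats[[length(feats) + 1L]] <- data.frame(
        genome_id = gid, start = tstart, end = pos, strand = "+",
        kind = "tRNA", label = "tRNA-Thr", stringsAsFactors = FALSE)
      add(draw_spacer(spacer_len[n_gaps]))
    }
  }
  list(seq = paste(parts, collapse = ""),
       proteins = prot_out,
       features = do.call(rbind, c(feats, list(make.row.names = FALSE))))
}

expand_pair_identity <- function(subs, spec) {
  ids <- subs$genome
  if (length(ids) < 2)
    return(data.frame(genome_a = character(0), genome_b = character(0),
                      planted_identity = numeric(0)))
  pr <- t(combn(ids, 2))
  same <- subs$subgroup[match(pr[, 1], subs$genome)] ==
    subs$subgroup[match(pr[, 2], subs$genome)]
  data.frame(genome_a = pr[, 1], genome_b = pr[, 2],
             planted_identity = ifelse(same, spec$within_divergence,
                                       spec$between_divergence),
             stringsAsFactors = FALSE)
}

#' Generate random decoy contigs (no phage genes)
#'
#' @param n number of contigs.
#' @param len_bp contig length.
#' @param seed integer seed.
#' @export
generate_decoys <- function(n = 80, len_bp = 40000, seed = 1) {
  with_seed(seed, {
    gcs <- runif(n, 0.35, 0.65)
    seqs <- vapply(gcs, function(p) paste(sample(
      c("A", "C", "G", "T"), len_bp, replace = TRUE,
      prob = c((1 - p) / 2, p / 2, p / 2, (1 - p) / 2)), collapse = ""),
      character(1))
    genome_set(sprintf("decoy_%03d", seq_len(n)), seqs, source = "host")
  })
}

#' Generate a bacterial host genome with a tRNA locus
#'
#' @param len_bp host contig length (default 60 kb).
#' @param gc host G+C fraction.
#' @param seed integer seed.
#' @return list: `genome` (one-row genome table), `features` (tRNA
#'   feature, 0-based half-open).
#' @export
generate_host <- function(len_bp = 60000, gc = 0.56, seed = 1) {
  with_seed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), len_bp, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
               collapse = "")
    tlen <- 72L
    tstart <- as.integer(len_bp / 2)
    g <- genome_set("host_1", s, source = "host")
    f <- feature_table("host_1", tstart, tstart + tlen, "+", "tRNA",
                       "tRNA-Thr")
    list(genome = g, features = f)
  })
}

#' Build a lysogen by Campbell integration at a planted att core
#'
#' A random `att_len` core is planted once in the phage (downstream of
#' the phage tRNA locus; attP) and once in the middle of the host tRNA
#' gene (attB).  The lysogen is host-prefix | core | phage-after-attP |
#' phage-before-attP | core | host-suffix, so its length equals host +
#' phage, and each of attL/attR contains the core exactly once.
#'
#' @param phage one-row genome table.
#' @param host one-row genome table.
#' @param host_trnas host tRNA feature table (as from [generate_host()]).
#' @param phage_trnas optional phage tRNA features (att planted after the
#'   first; defaults to 2/3 of the genome when absent).
#' @param att_len core length (default 13; >= 8).
#' @param seed integer seed.
#' @return list: `lysogen` (one-row genome table), `phage`, `host`
#'   (genome tables with the core planted), `host_features`, `truth`
#'   (list: `core`, 0-based half-open `attP`, `attB`, `attL`, `attR`).
#' @export
generate_lysogen <- function(phage, host, host_trnas, phage_trnas = NULL,
                             att_len = 13, seed = 1) {
  stopifnot(att_len >= 8)
  with_seed(seed, {
    trna <- host_trnas[host_trnas$kind == "tRNA", ][1, ]
    attB0 <- as.integer((trna$start + trna$end) / 2 - att_len / 2)
    attP0 <- if (!is.null(phage_trnas) && nrow(phage_trnas) > 0) {
      min(phage_trnas$end[1] + 40L, phage$length_bp - att_len - 1L)
    } else as.integer(phage$length_bp * 2 / 3)
    pseq <- phage$seq; hseq <- host$seq
    core <- NULL
    for (try in 1:100) {
      cand <- paste(sample(c("A", "C", "G", "T"), att_len, replace = TRUE),
                    collapse = "")
      p2 <- plant(pseq, cand, attP0)
      h2 <- plant(hseq, cand, attB0)
      if (count_occurrences(p2, cand) == 1 &&
          count_occurrences(h2, cand) == 1) {
        # force mismatching bases flanking the host copy so the maximal
        # exact match is exactly the planted core, and break any chance
        # phage/host match overlapping the tRNA locus that could
        # compete with the planted site
        h2 <- force_flank_mismatch(h2, p2, attB0, attP0, att_len)
        h2 <- break_trna_competitors(p2, h2, trna, attB0, att_len)
        if (count_occurrences(h2, cand) == 1) {
          core <- cand; pseq <- p2; hseq <- h2
          break
        }
      }
    }
    if (is.null(core)) stop("could not plant a unique att core in 100 tries")
    H1 <- substr(hseq, 1, attB0)
    H2 <- substr(hseq, attB0 + att_len + 1, nchar(hseq))
    P1 <- substr(pseq, 1, attP0)
    P2 <- substr(pseq, attP0 + att_len + 1, nchar(pseq))
    lys <- paste0(H1, core, P2, P1, core, H2)
    attL0 <- attB0                                  # first core copy
    attR0 <- attB0 + phage$length_bp                # second core copy
    lysogen <- genome_set(paste0(host$id, "_lysogen"), lys, source = "host")
    truth <- list(core = core,
                  attP = c(start = attP0, end = attP0 + att_len),
                  attB = c(start = attB0, end = attB0 + att_len),
                  attL = c(start = attL0, end = attL0 + att_len),
                  attR = c(start = attR0, end = attR0 + att_len))
    list(lysogen = lysogen,
         phage = genome_set(phage$id, pseq, source = phage$source),
         host = genome_set(host$id, hseq, source = "host"),
         host_features = host_trnas, truth = truth)
  })
}

# Break chance exact matches (>= att_len) between the phage and the
# host tRNA neighbourhood, other than the planted core, by flipping one
# host base per match; such matches would otherwise outrank the planted
# site in tRNA-overlap-first ordering.
break_trna_competitors <- function(phage, host, trna, attB0, att_len) {
  win0 <- max(0L, trna$start - 50L)
  win1 <- min(nchar(host), trna$end + 50L)
  core_lo <- attB0; core_hi <- attB0 + att_len
  for (pass in 1:5) {
    wseq <- substr(host, win0 + 1, win1)
    mm <- rbind(exact_matches(phage, wseq, att_len),
                within(exact_matches(phage, revcomp(wseq), att_len), {
                  tmp <- sstart
                  sstart <- nchar(wseq) - send
                  send <- nchar(wseq) - tmp
                  rm(tmp)
                })[, c("qstart", "qend", "sstart", "send")])
    if (nrow(mm) == 0) break
    mm$hs <- win0 + mm$sstart
    mm$he <- win0 + mm$send
    planted <- mm$hs == core_lo & mm$he == core_hi
    mm <- mm[!planted, , drop = FALSE]
    if (nrow(mm) == 0) break
    for (r in seq_len(nrow(mm))) {
      # flip the match base farthest from the planted core interval
      cand_pos <- setdiff(seq(mm$hs[r] + 1, mm$he[r]),
                          seq(core_lo + 1, core_hi))
      if (length(cand_pos) == 0) next
      mid <- (core_lo + core_hi) / 2
      pos <- cand_pos[which.max(abs(cand_pos - mid))]
      cur <- substr(host, pos, pos)
      repl <- setdiff(c("A", "C", "G", "T"), cur)[sample.int(3, 1)]
      substr(host, pos, pos) <- repl
    }
  }
  host
}

# make the host bases just outside the att core differ from the
# corresponding phage bases (keeps the exact match maximal at att_len)
force_flank_mismatch <- function(host, phage, attB0, attP0, att_len) {
  fix <- function(seq, pos, avoid) {
    cur <- substr(seq, pos, pos)
    if (cur != avoid) return(seq)
    repl <- setdiff(c("A", "C", "G", "T"), c(cur, avoid))[1]
    paste0(substr(seq, 1, pos - 1), repl,
           substr(seq, pos + 1, nchar(seq)))
  }
  if (attB0 >= 1 && attP0 >= 1)
    host <- fix(host, attB0, substr(phage, attP0, attP0))
  pb <- attB0 + att_len + 1L; pp <- attP0 + att_len + 1L
  if (pb <= nchar(host) && pp <= nchar(phage))
    host <- fix(host, pb, substr(phage, pp, pp))
  host
}

plant <- function(seq, core, pos0) {
  paste0(substr(seq, 1, pos0), core,
         substr(seq, pos0 + nchar(core) + 1, nchar(seq)))
}

count_occurrences <- function(seq, pat) {
  fw <- gregexpr(pat, seq, fixed = TRUE)[[1]]
  rv <- gregexpr(revcomp(pat), seq, fixed = TRUE)[[1]]
  sum(fw > 0) + sum(rv > 0)
}

# ---- read simulation ---------------------------------------------------

#' Simulate shotgun reads from a genome
#'
#' Uniform start positions, random strand, substitution errors only.
#'
#' @param seq genome sequence string.
#' @param n number of reads.
#' @param read_len read length (default 150).
#' @param err_rate per-base substitution rate.
#' @param seed integer seed.
#' @return character vector of reads.
#' @export
simulate_reads <- function(seq, n, read_len = 150, err_rate = 0.005,
                           seed = 1) {
  with_seed(seed, draw_reads(seq, n, read_len, err_rate))
}

draw_reads <- function(seq, n, read_len, err_rate) {
  L <- nchar(seq)
  stopifnot(L >= read_len)
  pos <- sample.int(L - read_len + 1L, n, replace = TRUE)
  reads <- substring(seq, pos, pos + read_len - 1L)
  rc <- runif(n) < 0.5
  reads[rc] <- revcomp(reads[rc])
  if (err_rate > 0) reads <- add_substitutions(reads, err_rate)
  reads
}

add_substitutions <- function(reads, err_rate) {
  if (length(reads) == 0) return(reads)
  rl <- nchar(reads[1])
  m <- matrix(charToRaw(paste(reads, collapse = "")), nrow = rl)
  nerr <- rbinom(1, length(m), err_rate)
  if (nerr > 0) {
    idx <- sample.int(length(m), nerr)
    bases <- charToRaw("ACGT")
    cur <- m[idx]
    repl <- bases[sample.int(4, nerr, replace = TRUE)]
    clash <- repl == cur
    while (any(clash)) {
      repl[clash] <- bases[sample.int(4, sum(clash), replace = TRUE)]
      clash <- repl == cur
    }
    m[idx] <- repl
  }
  apply(m, 2, rawToChar)
}

#' Abundance model for virome simulation
#'
#' Per-genome latitude effect: genomes with G+C above `gc_split` get
#' `+beta_scale`, below get `-beta_scale` (high-G+C phages more abundant
#' at high latitude / low temperature).  `low_gc_boost` multiplies the
#' baseline abundance of low-G+C genomes.
#'
#' @param beta_scale magnitude of the latitude effect (default 1).
#' @param gc_split G+C class boundary (default 0.45).
#' @param low_gc_boost baseline multiplier for low-G+C genomes.
#' @param noise_sd lognormal abundance noise (default 0.1).
#' @param beta optional named per-genome effect overriding the G+C rule.
#' @export
virome_model <- function(beta_scale = 1, gc_split = 0.45, low_gc_boost = 1,
                         noise_sd = 0.1, beta = NULL) {
  list(beta_scale = beta_scale, gc_split = gc_split,
       low_gc_boost = low_gc_boost, noise_sd = noise_sd, beta = beta)
}

#' Simulate virome read sets along an environmental gradient
#'
#' Samples span a northern-hemisphere latitude gradient; temperature is
#' anti-correlated with latitude by construction and salinity is
#' uncorrelated.  Per-sample expected relative abundance is
#' `a_gs ~ base_g * exp(beta_g * z_s + eps)` with `z_s` the standardized
#' latitude; reads are drawn per sample from genomes proportional to
#' `a_gs * length_g` with uniform substitution errors.
#'
#' @param genomes genome table (>= 1 genome).
#' @param n_samples number of samples (>= 3).
#' @param model a [virome_model()].
#' @param reads_per_sample reads drawn per sample.
#' @param read_len,err_rate read simulation parameters.
#' @param seed integer seed.
#' @return list: `reads` (named list sample -> character vector),
#'   `meta` (sample metadata: latitude, temperature, salinity, depth,
#'   biome), `truth` (per genome x sample: `rel_abundance`,
#'   `expected_read_prop`, `beta`, `counts`).
#' @export
simulate_viromes <- function(genomes, n_samples = 12, model = virome_model(),
                             reads_per_sample = 2000, read_len = 150,
                             err_rate = 0.005, seed = 1) {
  if (n_samples < 3) stop("need at least 3 samples for downstream correlation")
  with_seed(seed, {
    gc <- gc_content(genomes)
    beta <- model$beta %||%
      setNames(ifelse(gc >= model$gc_split, model$beta_scale,
                      -model$beta_scale), genomes$id)
    base <- ifelse(gc < model$gc_split, model$low_gc_boost, 1)
    lat <- seq(5, 70, length.out = n_samples)
    z <- as.numeric(scale(lat))
    temp <- 28 - 0.33 * lat + rnorm(n_samples, 0, 0.8)
    sal <- 35 + rnorm(n_samples, 0, 1.2)
    depth <- rep(5, n_samples)
    biome <- cut(lat, c(-Inf, 35, 60, Inf),
                 labels = c("trade", "westerlies", "polar"))
    samples <- sprintf("s%02d", seq_len(n_samples))
    meta <- data.frame(sample = samples, latitude = lat, temperature = temp,
                       salinity = sal, depth = depth,
                       biome = as.character(biome), stringsAsFactors = FALSE)
    ng <- nrow(genomes)
    reads <- list(); truth <- list()
    for (s in seq_len(n_samples)) {
      eps <- rnorm(ng, 0, model$noise_sd)
      a <- base * exp(beta[genomes$id] * z[s] + eps)
      a <- a / sum(a)
      p <- a * genomes$length_bp
      p <- p / sum(p)
      cnt <- as.integer(stats::rmultinom(1, reads_per_sample, p))
      rd <- character(0)
      for (g in seq_len(ng)) {
        if (cnt[g] == 0) next
        rd <- c(rd, draw_reads(genomes$seq[g], cnt[g], read_len, err_rate))
      }
      reads[[samples[s]]] <- rd
      truth[[s]] <- data.frame(genome = genomes$id, sample = samples[s],
                               rel_abundance = a, expected_read_prop = p,
                               beta = unname(beta[genomes$id]), counts = cnt,
                               stringsAsFactors = FALSE)
    }
    list(reads = reads, meta = meta,
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  })
}

#' Write reads as FASTQ (Phred+33, constant Q30)
#' @param reads character vector of reads.
#' @param path output path.
#' @param prefix read-id prefix.
#' @export
write_fastq <- function(reads, path, prefix = "read") {
  q <- strrep("?", nchar(reads))   # '?' = Q30 at Phred+33
  lines <- as.vector(rbind(paste0("@", prefix, "_", seq_along(reads)),
                           reads, "+", q))
  writeLines(lines, path)
  invisible(path)
}

#' Read a (plain) FASTQ file into a character vector of reads
#' @param path FASTQ path.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stop("truncated FASTQ")
  lines[seq(2, length(lines), by = 4)]
}

#' Seed alignments for the hallmark genes of a synthetic family
#'
#' Takes the planted hallmark protein from the first genome of each
#' subgroup and aligns them with [center_star_msa()]; these play the
#' role of the curated seed alignments a real analysis would start from.
#'
#' @param fam result of [generate_family()].
#' @param genes hallmark genes (default TerL, capsid, Prim-Pol).
#' @return named list of aligned named character vectors.
#' @export
hallmark_seed_msa <- function(fam, genes = c("TerL", "capsid", "PrimPol")) {
  subs <- fam$truth$subgroups
  reps <- subs$genome[!duplicated(subs$subgroup)]
  if (length(reps) < 2) reps <- subs$genome[seq_len(min(2, nrow(subs)))]
  out <- list()
  for (g in genes) {
    seqs <- setNames(
      vapply(reps, function(gm) fam$proteomes[[gm]][[paste0(gm, "_", g)]],
             character(1)), reps)
    out[[g]] <- center_star_msa(seqs, gene = g)$rows
  }
  out
}
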