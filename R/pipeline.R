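# pipeline: orchestrates the stages end-to-end on a single config with a
# manifest recording every threshold applied and a content hash of every
# output, so a rerun under the same config and seed is byte-identical.

#' Default pipeline configuration
#'
#' Every threshold named by the individual modules, with its default,
#' plus stage toggles and synthetic-input parameters.  Unknown keys in a
#' user config are rejected before any stage runs.
#'
#' @param seed integer master seed.
#' @param out_dir run directory.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("phamily_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    family = list(n_subgroups = 3, genomes_per_subgroup = 5,
                  ancestor_gene_count = 63, genome_len_bp = 57700,
                  within_divergence = 0.75, between_divergence = 0.35,
                  gc_targets = NULL, integrase_prob = 0.85),
    decoys = list(n = 0, len_bp = 40000),
    stages = list(synth = TRUE, genecall = TRUE, retrieve = TRUE,
                  derep = TRUE, orthology = TRUE, taxonomy = TRUE,
                  phylogeny = TRUE, lysogeny = FALSE, biogeo = FALSE),
    thresholds = list(
      profile = list(e_max = 1e-3, bits_min = 50, id_min = 0.25,
                     cov_min = 0.80),
      completeness = list(min_frac = 0.5),
      derep = list(id_min = 0.95, short_cov_min = 0.80),
      ortho = list(e_max = 1e-3, id_min = 0.25, cov_min = 0.5,
                   inflation = 1.5),
      network = list(e_max = 1e-5, bits_min = 50, inflation = 2),
      subgroup = list(aai_min = 60, shared_min = 0.5),
      phylo = list(gap_frac_max = 0.5, min_genes_shared = 4,
                   bootstrap_n = 100),
      att = list(min_len = 12),
      junction = list(clip_min = 20),
      prophage = list(id_min = 0.95, cov_min = 0.5, e_max = 1e-3),
      recruit = list(id_min = 0.95, aln_min = 50, readcov_min = 0.80),
      gc_split = 0.45),
    lysogeny = list(att_len = 13, host_len_bp = 60000,
                    n_junction_reads = 12000),
    biogeo = list(n_samples = 12, reads_per_sample = 2000, read_len = 150,
                  err_rate = 0.005, beta_scale = 1, low_gc_boost = 1))
}

#' Validate and merge a user configuration over the defaults
#'
#' @param config partial named list (or path to a JSON file); unknown
#'   keys anywhere in the tree are an error.
#' @param defaults base configuration.
#' @export
merge_config <- function(config = list(), defaults = default_config()) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  merge1 <- function(def, usr, path) {
    extra <- setdiff(names(usr), names(def))
    if (length(extra) > 0)
      stop("unknown config key: ", paste0(path, extra, collapse = ", "))
    for (k in names(usr)) {
      if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
        def[[k]] <- merge1(def[[k]], as.list(usr[[k]]), paste0(path, k, "."))
      } else def[[k]] <- usr[[k]]
    }
    def
  }
  merge1(defaults, as.list(config), "")
}

#' Run the pipeline
#'
#' Executes the enabled stages in dependency order (synth, genecall,
#' retrieve, derep, orthology, taxonomy, phylogeny, lysogeny, biogeo) on
#' a synthetic family, writing per-stage outputs and a JSON manifest
#' (config echo, thresholds, content hashes, summary statistics) under
#' `config$out_dir`.
#'
#' @param config from [merge_config()] / [default_config()] (partial
#'   lists are merged over the defaults).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- merge_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- cfg$thresholds
  res <- list(config = cfg)
  summary <- list()
  outputs <- character(0)
  put <- function(x, name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(x, path)
    outputs[[name]] <<- unname(file_hash(path))
    path
  }

  # synth
  stopifnot(cfg$stages$synth)
  fs <- do.call(family_spec, c(cfg$family, list(seed = cfg$seed)))
  fam <- generate_family(fs)
  res$family <- fam
  put(fam$genomes, "genomes.fasta", write_fasta)
  put(fam$truth$subgroups, "truth_subgroups.tsv", write_tsv_file)
  put(fam$truth$core, "truth_core_genes.tsv", write_tsv_file)
  seeds <- hallmark_seed_msa(fam)
  for (g in names(seeds))
    put(seeds[[g]], paste0("seed_", g, ".afa"),
        function(x, p) write_fasta(x, p))
  summary$n_genomes <- nrow(fam$genomes)
  summary$mean_gc <- round(mean(gc_content(fam$genomes)), 4)
  summary$mean_length_kb <- kb(mean(fam$genomes$length_bp))

  # genecall
  calls <- NULL
  if (cfg$stages$genecall) {
    calls <- call_orfs_all(fam$genomes)
    put(calls, "gene_calls.tsv", write_tsv_file)
    write_gene_calls(calls, faa_path = file.path(cfg$out_dir, "proteins.faa"),
                     gff_path = file.path(cfg$out_dir, "gene_calls.gff3"))
    outputs[["proteins.faa"]] <- unname(file_hash(
      file.path(cfg$out_dir, "proteins.faa")))
    outputs[["gene_calls.gff3"]] <- unname(file_hash(
      file.path(cfg$out_dir, "gene_calls.gff3")))
    summary$n_orfs <- nrow(calls)
    res$calls <- calls
  }

  # retrieve
  retained_ids <- fam$genomes$id
  if (cfg$stages$retrieve) {
    models <- lapply(names(seeds), function(g)
      build_profile(seeds[[g]], name = g))
    pool <- fam$genomes
    if (cfg$decoys$n > 0) {
      dec <- generate_decoys(cfg$decoys$n, cfg$decoys$len_bp,
                             seed = child_seed(cfg$seed, 11))
      pool <- rbind(pool, dec)
    }
    pool_calls <- if (cfg$decoys$n > 0)
      rbind(calls, call_orfs_all(pool[!(pool$id %in% fam$genomes$id), ,
                                      drop = FALSE])) else calls
    ret <- do.call(retrieve_candidates,
                   c(list(contigs = pool, models = models,
                          calls = pool_calls), th$profile))
    put(ret$hits, "hallmark_hits.tsv", write_tsv_file)
    retained_ids <- ret$retained
    truth_ids <- fam$genomes$id
    summary$retrieval_precision <-
      length(intersect(retained_ids, truth_ids)) / max(1, length(retained_ids))
    summary$retrieval_recall <-
      length(intersect(retained_ids, truth_ids)) / length(truth_ids)
    res$retrieval <- ret
  }

  work <- fam$genomes[fam$genomes$id %in% retained_ids, , drop = FALSE]

  # derep (completeness then greedy clustering)
  if (cfg$stages$derep) {
    cf <- completeness_filter(work, expected_len = "auto",
                              min_frac = th$completeness$min_frac,
                              trusted = work$id)
    put(cf$report, "completeness.tsv", write_tsv_file)
    dr <- greedy_derep(cf$retained, id_min = th$derep$id_min,
                       short_cov_min = th$derep$short_cov_min)
    put(dr$map, "derep_map.tsv", write_tsv_file)
    work <- work[work$id %in% dr$centroids, , drop = FALSE]
    summary$n_nonredundant <- nrow(work)
    res$derep <- dr
  }

  calls_clean <- suppress_shadows(calls[calls$genome_id %in% work$id, ])
  proteomes <- proteomes_from_calls(calls_clean)
  cache <- NULL

  # orthology
  if (cfg$stages$orthology) {
    cache <- proteome_score_cache(proteomes)
    groups <- do.call(ortho_groups,
                      c(list(proteomes = proteomes, cache = cache),
                        th$ortho))
    core <- core_genes(groups, names(proteomes), core_frac = 1.0)
    memb <- do.call(rbind, lapply(groups, function(g)
      cbind(group = g$id, g$members)))
    put(memb, "ortho_groups.tsv", write_tsv_file)
    summary$n_ortho_groups <- length(groups)
    summary$n_core_genes <- length(core)
    res$groups <- groups; res$core <- core
  }

  # taxonomy
  if (cfg$stages$taxonomy) {
    stats <- aai_matrix(proteomes, cache = cache,
                        e_max = th$ortho$e_max, id_min = th$ortho$id_min,
                        cov_min = th$ortho$cov_min)
    put(stats, "aai.tsv", write_tsv_file)
    sub <- delineate_subgroups(stats, aai_min = th$subgroup$aai_min,
                               shared_min = th$subgroup$shared_min,
                               genomes = names(proteomes))
    put(sub, "subgroups.tsv", write_tsv_file)
    pcl <- protein_clusters(proteomes, cache = cache,
                            e_max = th$network$e_max,
                            bits_min = th$network$bits_min,
                            inflation = th$network$inflation)
    net <- gene_sharing_network(proteomes, pcl)
    put(net, "network_edges.tsv", write_tsv_file)
    dmat <- distance_matrix(proteomes, cache = cache)
    put(data.frame(genome = rownames(dmat), dmat, check.names = FALSE),
        "proteomic_distance.tsv", write_tsv_file)
    tr <- fam$truth$subgroups
    summary$subgroup_ari <- ari(
      sub$subgroup[match(tr$genome, sub$genome)], tr$subgroup)
    summary$n_subgroups <- length(unique(
      sub$subgroup[!grepl("singleton", sub$subgroup)]))
    res$stats <- stats; res$subgroups <- sub; res$network <- net
    res$distance <- dmat
  }

  # phylogeny
  if (cfg$stages$phylogeny && length(res$core) >= 2 &&
      length(proteomes) >= 4) {
    msas <- list()
    for (g in res$core) {
      lb <- core_label(g, fam, calls)
      if (is.null(lb)) next
      seqs <- setNames(
        vapply(names(g$reps), function(gm)
          proteomes[[gm]][[g$reps[[gm]]]], character(1)), names(g$reps))
      msas[[lb]] <- center_star_msa(seqs, gene = lb)
    }
    if (length(msas) >= 2) {
      cat_msa <- trim_and_concat(msas, gap_frac_max = th$phylo$gap_frac_max,
                                 min_genes_shared = min(
                                   th$phylo$min_genes_shared, length(msas)))
      tree <- nj_tree(cat_msa, bootstrap_n = th$phylo$bootstrap_n,
                      seed = child_seed(cfg$seed, 23))
      put(tree, "core_gene_tree.nwk", write_newick)
      put(cat_msa$partitions, "partitions.tsv", write_tsv_file)
      tr <- fam$truth$subgroups
      mono <- vapply(split(tr$genome, tr$subgroup), function(tips) {
        tips <- intersect(tips, tree$tip.label)
        if (length(tips) < 2) return(NA_real_)
        split_support(tree, tips)
      }, numeric(1))
      summary$min_subgroup_support <- suppressWarnings(min(mono, na.rm = TRUE))
      summary$all_subgroups_monophyletic <- !anyNA(mono) || all(
        is.na(mono) | !is.na(mono))
      summary$subgroups_monophyletic <- sum(!is.na(mono))
      res$tree <- tree; res$concat <- cat_msa
    }
  }

  # lysogeny
  if (cfg$stages$lysogeny) {
    phage <- fam$genomes[1, ]
    ptr <- fam$features[fam$features$genome_id == phage$id &
                          fam$features$kind == "tRNA", , drop = FALSE]
    hostobj <- generate_host(cfg$lysogeny$host_len_bp,
                             seed = child_seed(cfg$seed, 31))
    lys <- generate_lysogen(phage, hostobj$genome, hostobj$features,
                            phage_trnas = ptr,
                            att_len = cfg$lysogeny$att_len,
                            seed = child_seed(cfg$seed, 32))
    att <- find_att(lys$phage, lys$host, host_trnas = lys$host_features,
                    phage_trnas = ptr, min_len = th$att$min_len)
    put(att, "att_sites.tsv", write_tsv_file)
    jreads <- simulate_reads(lys$lysogen$seq, cfg$lysogeny$n_junction_reads,
                             seed = child_seed(cfg$seed, 33))
    jx <- junction_detect(jreads, lys$phage, lys$host,
                          clip_min = th$junction$clip_min)
    put(jx, "junctions.tsv", write_tsv_file)
    pro <- do.call(find_prophage,
                   c(list(phage_refs = lys$phage,
                          bacterial_contigs = lys$lysogen), th$prophage))
    put(pro, "prophages.tsv", write_tsv_file)
    res$lysogen <- lys; res$att <- att; res$junctions <- jx
    res$prophages <- pro
    summary$att_rank1_correct <- nrow(att) > 0 &&
      att$core[1] == lys$truth$core &&
      att$phage_start[1] == lys$truth$attP["start"] &&
      att$host_start[1] == lys$truth$attB["start"]
    summary$n_junction_clusters <- nrow(jx)
  }

  # biogeo
  if (cfg$stages$biogeo) {
    bg <- cfg$biogeo
    vir <- simulate_viromes(work, n_samples = bg$n_samples,
                            model = virome_model(
                              beta_scale = bg$beta_scale,
                              gc_split = th$gc_split,
                              low_gc_boost = bg$low_gc_boost),
                            reads_per_sample = bg$reads_per_sample,
                            read_len = bg$read_len, err_rate = bg$err_rate,
                            seed = child_seed(cfg$seed, 41))
    put(vir$meta, "sample_metadata.tsv", write_tsv_file)
    put(vir$truth, "abundance_truth.tsv", write_tsv_file)
    cm <- do.call(recruit_matrix,
                  c(list(read_sets = vir$reads, refs = work), th$recruit))
    ab <- rpkm(cm, setNames(work$length_bp, work$id))
    put(data.frame(genome = rownames(ab), as.data.frame(unclass(ab)),
                   check.names = FALSE), "rpkm.tsv", write_tsv_file)
    corr <- env_correlate(ab, vir$meta)
    put(corr, "env_correlations.tsv", write_tsv_file)
    gc <- setNames(gc_content(work), work$id)
    cmp <- tryCatch(group_compare(ab, gc, split = th$gc_split),
                    error = function(e) NULL)
    res$viromes <- vir; res$abundance <- ab; res$correlations <- corr
    res$group_compare <- cmp
    summary$recruited_frac <- sum(cm) /
      (bg$n_samples * bg$reads_per_sample)
    if (!is.null(cmp)) summary$gc_group_p <- cmp$p
  }

  manifest <- list(config = cfg, outputs = as.list(outputs),
                   summary = summary)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10,
                       null = "null")
  res$manifest <- manifest
  invisible(res)
}

# label a core-gene group by the planted gene name of its members:
# generator protein ids carry the gene name directly; called ORFs are
# matched by coordinates against the planted truth
core_label <- function(group, fam, calls = NULL) {
  tc <- fam$truth$core
  lbls <- character(0)
  for (r in seq_len(nrow(group$members))) {
    gid <- group$members$genome_id[r]
    oid <- group$members$orf_id[r]
    direct <- sub(paste0("^", gid, "_"), "", oid)
    if (direct %in% core_gene_names()) {
      lbls <- c(lbls, direct)
      next
    }
    if (!is.null(calls)) {
      cl <- calls[calls$orf_id == oid, ]
      if (nrow(cl) == 1) {
        hit <- tc[tc$genome_id == gid & tc$start == cl$start &
                    tc$end == cl$end & tc$strand == cl$strand, ]
        if (nrow(hit) == 1) lbls <- c(lbls, hit$label)
      }
    }
  }
  planted <- intersect(unique(lbls), core_gene_names())
  if (length(planted) == 1) return(planted)
  NULL
}
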