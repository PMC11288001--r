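# taxonomy: ortholog groups, core genes, average amino-acid identity
# (AAI), shared-gene fraction, hypergeometric gene-sharing network,
# proteomic distance, and subgroup delineation.
#
# Proteomes are a named list: genome id -> named character vector of
# protein sequences (orf id -> sequence), e.g. from proteomes_from_calls().

#' Split gene calls into per-genome proteomes
#' @param calls data.frame from [call_orfs_all()].
#' @export
proteomes_from_calls <- function(calls) {
  lapply(split(calls, calls$genome_id), function(d)
    setNames(d$protein, d$orf_id))
}

# ---- shared all-vs-all score cache -------------------------------------
# Local raw scores between all proteins with score >= min_raw, plus self
# scores and lazy full alignments.  min_raw = 60 sits safely below every
# gate used downstream (bits >= 50 corresponds to raw ~103; the e-value
# gates to raw ~75-80 at desk-scale search spaces).

#' Precompute the all-vs-all protein score table
#'
#' @param proteomes named list of named protein vectors.
#' @param min_raw floor on stored raw local scores.
#' @return an opaque cache object consumed by [ortho_groups()],
#'   [aai_matrix()], [distance_matrix()] and [protein_clusters()].
#' @export
proteome_score_cache <- function(proteomes, min_raw = 60) {
  prot <- unlist(unname(lapply(proteomes, as.list)), recursive = FALSE)
  prot <- setNames(unlist(prot), unlist(lapply(proteomes, names)))
  if (anyDuplicated(names(prot))) stop("duplicate orf ids across proteomes")
  genome_of <- rep(names(proteomes), vapply(proteomes, length, integer(1)))
  names(genome_of) <- names(prot)
  m <- aa_matrix()
  enc <- lapply(prot, aa_encode, alphabet = rownames(m))
  tri <- cpp_allvsall_scores(enc, m, 11, 1, min_raw,
                             matrix(integer(0), 0, 2))
  dt <- data.table::data.table(i = tri$i, j = tri$j, score = tri$score)
  selfscore <- vapply(seq_along(enc), function(k)
    sum(m[cbind(enc[[k]] + 1L, enc[[k]] + 1L)]), numeric(1))
  env <- new.env(parent = emptyenv())
  env$aligned <- data.table::data.table(i = integer(0), j = integer(0),
                                        identity = numeric(0),
                                        cov_i = numeric(0), cov_j = numeric(0),
                                        matches = integer(0),
                                        cols = integer(0))
  list(ids = names(prot), prot = prot, plen = nchar(prot),
       genome_of = genome_of, enc = enc, mat = m, scores = dt,
       selfscore = selfscore, min_raw = min_raw, env = env)
}

# full alignments (identity, per-side coverage) for index pairs (i < j),
# memoised in the cache environment
cache_alignments <- function(cache, pairs) {
  if (nrow(pairs) == 0)
    return(cache$env$aligned[0])
  pairs <- unique(data.table::data.table(i = pmin(pairs$i, pairs$j),
                                         j = pmax(pairs$i, pairs$j)))
  have <- cache$env$aligned[, c("i", "j")]
  need <- pairs[!have, on = c("i", "j")]
  if (nrow(need) > 0) {
    rows <- lapply(seq_len(nrow(need)), function(r) {
      a <- need$i[r]; b <- need$j[r]
      al <- cpp_pair_align(cache$enc[[a]], cache$enc[[b]], cache$mat,
                           11, 1, TRUE)
      data.table::data.table(
        i = a, j = b,
        identity = if (al$aligned_cols > 0) al$matches / al$aligned_cols else 0,
        cov_i = al$q_aligned / cache$plen[a],
        cov_j = al$s_aligned / cache$plen[b],
        matches = al$matches, cols = al$aligned_cols)
    })
    cache$env$aligned <- data.table::rbindlist(
      c(list(cache$env$aligned), rows))
  }
  cache$env$aligned[pairs, on = c("i", "j")]
}

# symmetric long view of the score table restricted to two genomes
pair_scores <- function(cache, ga, gb) {
  ia <- which(cache$genome_of == ga)
  ib <- which(cache$genome_of == gb)
  dt <- cache$scores[(i %in% ia & j %in% ib) | (i %in% ib & j %in% ia)]
  dt
}

# ---- orthology ---------------------------------------------------------

#' Detect ortholog groups
#'
#' Builds a protein similarity graph with BLASTp-style gates
#' (e-value <= e_max, identity >= id_min, query-side coverage >= cov_min),
#' weights edges by bit score, runs Markov clustering (inflation 1.5, the
#' granularity convention of ortholog-detection tools), and
#' reports clusters with at least two members.
#'
#' @param proteomes named list of proteomes (>= 2 genomes).
#' @param cache optional [proteome_score_cache()] (computed otherwise).
#' @param e_max,id_min,cov_min edge gates (defaults 1e-3, 0.25, 0.50).
#' @param inflation MCL inflation.
#' @return list of groups: each `list(id, members)` with `members` a
#'   data.frame (genome_id, orf_id); plus attribute `"thresholds"`.
#' @export
ortho_groups <- function(proteomes, cache = NULL, e_max = 1e-3,
                         id_min = 0.25, cov_min = 0.5, inflation = 1.5) {
  if (length(proteomes) < 2) stop("need at least two genomes")
  if (is.null(cache)) cache <- proteome_score_cache(proteomes)
  nsub <- length(cache$ids)
  dt <- cache$scores
  if (nrow(dt) > 0) {
    al <- cache_alignments(cache, dt)
    bits <- bit_score(dt$score)
    ev <- as.numeric(cache$plen[dt$i]) * cache$plen[dt$j] * nsub * 2^(-bits)
    # query-side coverage: gate passes if either orientation would pass
    qcov <- pmax(al$cov_i, al$cov_j)
    keep <- ev <= e_max & al$identity >= id_min & qcov >= cov_min
    edges <- data.frame(from = cache$ids[dt$i[keep]],
                        to = cache$ids[dt$j[keep]],
                        weight = bits[keep], stringsAsFactors = FALSE)
  } else edges <- data.frame(from = character(0), to = character(0),
                             weight = numeric(0))
  res <- mcl(edges, inflation = inflation)
  groups <- Filter(function(g) length(g) >= 2, res$clusters)
  groups <- groups[order(-lengths(groups),
                         vapply(groups, function(g) sort(g)[1], character(1)))]
  out <- lapply(seq_along(groups), function(k) {
    ids <- sort(groups[[k]])
    list(id = sprintf("OG%04d", k),
         members = data.frame(genome_id = unname(cache$genome_of[ids]),
                              orf_id = ids, stringsAsFactors = FALSE))
  })
  attr(out, "thresholds") <- list(e_max = e_max, id_min = id_min,
                                  cov_min = cov_min, inflation = inflation)
  out
}

#' Core-gene groups
#'
#' Groups present (>= 1 member) in at least `core_frac` of the genomes.
#' One representative per genome is chosen: the member with the highest
#' mean in-group alignment score (ties: lexicographically first orf id).
#'
#' @param groups from [ortho_groups()].
#' @param genomes character vector of genome ids (the universe).
#' @param core_frac presence fraction required (default 1.0).
#' @return subset of `groups`, each with an added `reps` element
#'   (named character vector: genome id -> representative orf id).
#' @export
core_genes <- function(groups, genomes, core_frac = 1.0) {
  out <- list()
  for (g in groups) {
    present <- unique(g$members$genome_id)
    if (length(intersect(present, genomes)) < core_frac * length(genomes))
      next
    reps <- vapply(split(g$members$orf_id, g$members$genome_id),
                   function(ids) sort(ids)[1], character(1))
    g$reps <- reps
    out[[length(out) + 1L]] <- g
  }
  out
}

# ---- AAI / shared genes ------------------------------------------------

# best gated hits of genome A's proteins in genome B (direction A -> B)
best_hits_dir <- function(cache, ga, gb, e_max, id_min, cov_min) {
  dt <- pair_scores(cache, ga, gb)
  if (nrow(dt) == 0) return(NULL)
  # orient: q in A, s in B
  qa <- ifelse(cache$genome_of[dt$i] == ga, dt$i, dt$j)
  sb <- ifelse(cache$genome_of[dt$i] == ga, dt$j, dt$i)
  d <- data.table::data.table(q = qa, s = sb, score = dt$score)
  d <- d[order(q, -score, cache$ids[s])]
  best <- d[!duplicated(q)]
  al <- cache_alignments(cache, data.table::data.table(i = best$q, j = best$s))
  qcov <- ifelse(best$q < best$s, al$cov_i, al$cov_j)
  nB <- sum(cache$genome_of == gb)
  ev <- as.numeric(cache$plen[best$q]) * cache$plen[best$s] * nB *
    2^(-bit_score(best$score))
  keep <- ev <= e_max & al$identity >= id_min & qcov >= cov_min
  if (!any(keep)) return(NULL)
  data.table::data.table(q = best$q[keep], s = best$s[keep],
                         score = best$score[keep],
                         identity = al$identity[keep])
}

#' Average amino-acid identity between two proteomes
#'
#' Reciprocal-best-hit (RBH) AAI: best local hits in both directions
#' (gates: e-value <= 1e-3, identity >= 0.25, query coverage >= 0.5);
#' AAI is the unweighted mean percent identity over RBH pairs, and the
#' shared-gene fraction is the RBH count over the smaller gene count.
#' AAI is `NA` when there are no RBH pairs.
#'
#' @param pa,pb named protein vectors (one proteome each); or use
#'   [aai_matrix()] for all pairs at once.
#' @param e_max,id_min,cov_min hit gates.
#' @return one-row data.frame: genome_a, genome_b, aai (percent),
#'   rbh_count, shared_frac.
#' @export
aai <- function(pa, pb, e_max = 1e-3, id_min = 0.25, cov_min = 0.5) {
  if (length(pa) == 0 || length(pb) == 0) stop("empty proteome")
  if (any(names(pa) %in% names(pb))) {  # e.g. a genome against itself
    names(pa) <- paste0("A|", names(pa))
    names(pb) <- paste0("B|", names(pb))
  }
  aai_matrix(list(A = pa, B = pb), e_max = e_max,
             id_min = id_min, cov_min = cov_min)
}

#' Pairwise genome statistics (AAI, shared-gene fraction) for all pairs
#'
#' @param proteomes named list of proteomes.
#' @param cache optional [proteome_score_cache()].
#' @inheritParams aai
#' @return data.frame with one row per unordered genome pair:
#'   genome_a, genome_b, aai, rbh_count, shared_frac.
#' @export
aai_matrix <- function(proteomes, cache = NULL, e_max = 1e-3,
                       id_min = 0.25, cov_min = 0.5) {
  if (any(lengths(proteomes) == 0)) stop("empty proteome")
  if (is.null(cache)) cache <- proteome_score_cache(proteomes)
  gs <- names(proteomes)
  rows <- list()
  for (a in seq_along(gs)) for (b in seq_len(a - 1L)) {
    ga <- gs[b]; gb <- gs[a]
    fw <- best_hits_dir(cache, ga, gb, e_max, id_min, cov_min)
    bw <- best_hits_dir(cache, gb, ga, e_max, id_min, cov_min)
    if (is.null(fw) || is.null(bw)) {
      rbh <- data.table::data.table()
    } else {
      rbh <- merge(fw, bw[, .(q = s, s = q)], by = c("q", "s"))
    }
    n_rbh <- nrow(rbh)
    rows[[length(rows) + 1L]] <- data.frame(
      genome_a = ga, genome_b = gb,
      aai = if (n_rbh > 0) 100 * mean(rbh$identity) else NA_real_,
      rbh_count = n_rbh,
      shared_frac = n_rbh / min(length(proteomes[[ga]]),
                                length(proteomes[[gb]])),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# ---- gene-sharing network ---------------------------------------------

#' Cluster all proteins for the gene-sharing network
#'
#' All-vs-all local alignment with the network gates
#' (e-value < 1e-5, bits >= 50), then MCL on the bitscore-weighted graph.
#' Singleton proteins form their own clusters so that the cluster
#' universe covers every protein.
#'
#' @param proteomes named list of proteomes.
#' @param cache optional score cache.
#' @param e_max,bits_min network protein-graph gates.
#' @param inflation MCL inflation.
#' @return [mcl()] result over all protein ids.
#' @export
protein_clusters <- function(proteomes, cache = NULL, e_max = 1e-5,
                             bits_min = 50, inflation = 2) {
  if (is.null(cache)) cache <- proteome_score_cache(proteomes)
  dt <- cache$scores
  bits <- bit_score(dt$score)
  nsub <- length(cache$ids)
  ev <- as.numeric(cache$plen[dt$i]) * cache$plen[dt$j] * nsub * 2^(-bits)
  keep <- bits >= bits_min & ev < e_max
  edges <- data.frame(from = cache$ids[dt$i[keep]],
                      to = cache$ids[dt$j[keep]],
                      weight = bits[keep], stringsAsFactors = FALSE)
  mcl(edges, inflation = inflation, nodes = cache$ids)
}

#' Hypergeometric gene-sharing network between genomes
#'
#' For a genome pair with `a` and `b` protein clusters of which `c` are
#' shared, out of `N` clusters in total, the edge significance is the
#' hypergeometric survival probability
#' `P = sum_{i=c}^{min(a,b)} C(a,i) C(N-a,b-i) / C(N,b)`; the edge score
#' is `max(0, -log10 P - log10 T)` with `T` the number of genome pairs,
#' and edges with score >= 1 are kept.
#'
#' @param proteomes named list of proteomes.
#' @param clusters [mcl()] result over all proteins (see
#'   [protein_clusters()]).
#' @param min_score edge retention threshold (default 1).
#' @return data.frame: source, target, shared (c), n_source (a),
#'   n_target (b), p, score; attribute `"n_clusters"` = N.
#' @export
gene_sharing_network <- function(proteomes, clusters, min_score = 1) {
  cl <- clusters$clusters
  N <- length(cl)
  member_cluster <- rep(seq_along(cl), lengths(cl))
  names(member_cluster) <- unlist(cl)
  sets <- lapply(proteomes, function(p) {
    s <- unique(member_cluster[names(p)])
    sort(s[!is.na(s)])
  })
  gs <- names(proteomes)
  Tpairs <- choose(length(gs), 2)
  rows <- list()
  for (x in seq_along(gs)) for (y in seq_len(x - 1L)) {
    a <- length(sets[[y]]); b <- length(sets[[x]])
    if (N < max(a, b)) stop("cluster universe smaller than a genome's clusters")
    c_sh <- length(intersect(sets[[y]], sets[[x]]))
    p <- hyper_shared_p(c_sh, a, b, N)
    score <- max(0, -log10(p) - log10(Tpairs))
    rows[[length(rows) + 1L]] <- data.frame(
      source = gs[y], target = gs[x], shared = c_sh, n_source = a,
      n_target = b, p = p, score = score, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[out$score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_clusters") <- N
  out
}

#' Hypergeometric survival probability of sharing >= c clusters
#' @param c_shared,a,b,n observed shared count, set sizes, universe size.
#' @export
hyper_shared_p <- function(c_shared, a, b, n) {
  if (c_shared == 0) return(1)
  phyper(c_shared - 1, a, n - a, b, lower.tail = FALSE)
}

# ---- subgroups ---------------------------------------------------------

#' Delineate subgroups from AAI and shared-gene gates
#'
#' Genomes are connected when `aai > aai_min` and
#' `shared_frac > shared_min`; subgroups are connected components of
#' size >= 2, labelled with roman numerals in decreasing size order
#' (ties: lexicographically smallest member id), and size-1 components
#' are labelled `singleton-k` in order of member id.
#'
#' @param stats data.frame from [aai_matrix()].
#' @param aai_min,shared_min gates on percent AAI and shared fraction
#'   (defaults 60 and 0.5; strict `>`).
#' @param genomes optional universe of genome ids (defaults to ids seen
#'   in `stats`).
#' @return data.frame (genome, subgroup); attribute `"thresholds"`.
#' @export
delineate_subgroups <- function(stats, aai_min = 60, shared_min = 0.5,
                                genomes = NULL) {
  if (is.null(genomes))
    genomes <- sort(unique(c(stats$genome_a, stats$genome_b)))
  ok <- !is.na(stats$aai) & stats$aai > aai_min &
    stats$shared_frac > shared_min
  g <- igraph::graph_from_data_frame(
    stats[ok, c("genome_a", "genome_b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = genomes))
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  big <- Filter(function(x) length(x) >= 2, groups)
  small <- Filter(function(x) length(x) == 1, groups)
  big <- big[order(-lengths(big),
                   vapply(big, function(x) sort(x)[1], character(1)))]
  small <- small[order(vapply(small, `[[`, character(1), 1))]
  lab <- c(setNames(rep(roman(seq_along(big)), lengths(big)),
                    unlist(big)),
           setNames(paste0("singleton-", seq_along(small)), unlist(small)))
  out <- data.frame(genome = genomes, subgroup = unname(lab[genomes]),
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- list(aai_min = aai_min, shared_min = shared_min,
                                  method = "connected-components")
  out
}

# ---- proteomic distance ------------------------------------------------

#' Normalised proteomic distance between two proteomes
#'
#' `S_AB` is the sum over A's proteins of the best gated hit bit score
#' in B (gates as in [aai()]); the distance is
#' `1 - (S_AB + S_BA) / 2 / sqrt(S_AA * S_BB)`, clamped to `[0, 1]`,
#' and 1 when there are no hits.
#'
#' @inheritParams aai
#' @export
proteomic_distance <- function(pa, pb, e_max = 1e-3, id_min = 0.25,
                               cov_min = 0.5) {
  dm <- distance_matrix(list(A = pa, B = pb), e_max = e_max,
                        id_min = id_min, cov_min = cov_min)
  dm["A", "B"]
}

#' Proteomic distance matrix over a set of proteomes
#' @inheritParams aai_matrix
#' @export
distance_matrix <- function(proteomes, cache = NULL, e_max = 1e-3,
                            id_min = 0.25, cov_min = 0.5) {
  if (any(lengths(proteomes) == 0)) stop("empty proteome")
  if (is.null(cache)) cache <- proteome_score_cache(proteomes)
  gs <- names(proteomes)
  selfsum <- vapply(gs, function(g)
    sum(bit_score(cache$selfscore[cache$genome_of == g])), numeric(1))
  D <- matrix(0, length(gs), length(gs), dimnames = list(gs, gs))
  for (x in seq_along(gs)) for (y in seq_len(x - 1L)) {
    fw <- best_hits_dir(cache, gs[y], gs[x], e_max, id_min, cov_min)
    bw <- best_hits_dir(cache, gs[x], gs[y], e_max, id_min, cov_min)
    sab <- if (is.null(fw)) 0 else sum(bit_score(fw$score))
    sba <- if (is.null(bw)) 0 else sum(bit_score(bw$score))
    if (sab + sba == 0) {
      d <- 1
    } else {
      d <- 1 - ((sab + sba) / 2) / sqrt(selfsum[x] * selfsum[y])
      d <- min(1, max(0, d))
    }
    D[x, y] <- D[y, x] <- d
  }
  D
}
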