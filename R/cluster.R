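# cluster: completeness filtering (length proxy), greedy incremental
# dereplication (CD-HIT convention: longest-first, coverage of the
# shorter sequence), and Markov clustering shared by the orthology and
# network stages.

#' Length-proxy completeness filter
#'
#' Completeness is `min(1, length / expected_len)`; genomes strictly
#' below `min_frac` are dropped.  This is a deliberate proxy for
#' model-based completeness estimators and is labelled as such in the
#' report.
#'
#' @param genomes genome table.
#' @param expected_len expected complete-genome length in bp, or
#'   `"auto"` to use the median length of the trusted genomes.
#' @param min_frac drop threshold (default 0.5; "< min_frac" drops).
#' @param trusted ids of trusted complete genomes (required for
#'   `"auto"`).
#' @return list with `retained` (genome table) and `report`
#'   (id, length_bp, completeness, retained).
#' @export
completeness_filter <- function(genomes, expected_len = "auto",
                                min_frac = 0.5, trusted = NULL) {
  if (identical(expected_len, "auto")) {
    if (is.null(trusted) || !any(genomes$id %in% trusted))
      stop("expected_len = 'auto' needs at least one trusted genome")
    expected_len <- median(genomes$length_bp[genomes$id %in% trusted])
  }
  comp <- pmin(1, genomes$length_bp / expected_len)
  keep <- comp >= min_frac
  list(retained = genomes[keep, , drop = FALSE],
       report = data.frame(id = genomes$id, length_bp = genomes$length_bp,
                           completeness = comp, retained = keep,
                           method = "length-proxy",
                           stringsAsFactors = FALSE))
}

# identity and coverage-of-query between two nucleotide sequences from
# seed-and-extend segments (segments are query-non-overlapping)
nt_identity_cov <- function(q, s, k = 15, cache = NULL) {
  hits <- nt_seed_extend(q, s, k = k, cache = cache)
  if (nrow(hits) == 0) return(c(identity = 0, coverage = 0))
  c(identity = sum(hits$matches) / sum(hits$aligned_cols),
    coverage = sum(hits$aligned_cols) / nchar(unname(q)))
}

#' Greedy incremental dereplication
#'
#' Sequences are sorted by length descending (ties broken by
#' lexicographic id) and each joins the first existing centroid with
#' identity `>= id_min` and coverage-of-the-shorter `>= short_cov_min`
#' (both measured on seed-and-extend segments), else founds a new
#' centroid.
#'
#' @param seqs named character vector of nucleotide sequences, or a
#'   genome table.
#' @param id_min,short_cov_min clustering gates (defaults 0.95 / 0.80).
#' @return list: `centroids` (ids), `map` (member, centroid, identity,
#'   coverage; centroids map to themselves at identity 1).
#' @export
greedy_derep <- function(seqs, id_min = 0.95, short_cov_min = 0.80) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  centroids <- character(0)
  rows <- list()
  kcache <- new.env(parent = emptyenv())
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    assigned <- FALSE
    for (cid in centroids) {
      ic <- nt_identity_cov(setNames(seqs[[i]], id), setNames(seqs[[cid]], cid),
                            cache = kcache)
      if (ic["identity"] >= id_min && ic["coverage"] >= short_cov_min) {
        rows[[i]] <- data.frame(member = id, centroid = cid,
                                identity = unname(ic["identity"]),
                                coverage = unname(ic["coverage"]),
                                stringsAsFactors = FALSE)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      centroids <- c(centroids, id)
      rows[[i]] <- data.frame(member = id, centroid = id, identity = 1,
                              coverage = 1, stringsAsFactors = FALSE)
    }
  }
  list(centroids = centroids, map = do.call(rbind, rows))
}

#' Markov clustering (MCL)
#'
#' Standard expansion (matrix power 2) / inflation iteration on the
#' column-stochastic transition matrix of a weighted undirected graph.
#' Self-loops of weight equal to each node's maximum incident weight are
#' added before normalisation.  Clusters are the connected components of
#' the limit matrix's support.
#'
#' @param edges data.frame with columns `from`, `to`, `weight`
#'   (non-negative), or a 2-3 column matrix-like (weight defaults to 1).
#' @param inflation inflation exponent (default 2).
#' @param max_iter,prune,tol iteration controls.
#' @param nodes optional full node set (to include isolated nodes).
#' @return list: `clusters` (list of character vectors partitioning the
#'   node set), `inflation`, `iterations`.
#' @export
mcl <- function(edges, inflation = 2, max_iter = 100, prune = 1e-5,
                tol = 1e-6, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    if (is.null(nodes) || length(nodes) == 0)
      return(list(clusters = list(), inflation = inflation, iterations = 0L))
    return(list(clusters = as.list(nodes), inflation = inflation,
                iterations = 0L))
  }
  ed <- data.frame(from = as.character(edges[[1]]),
                   to = as.character(edges[[2]]),
                   weight = if (ncol(edges) >= 3) as.numeric(edges[[3]]) else 1,
                   stringsAsFactors = FALSE)
  stopifnot(all(ed$weight >= 0))
  ids <- unique(c(ed$from, ed$to, nodes))
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  fi <- match(ed$from, ids); ti <- match(ed$to, ids)
  for (r in seq_along(fi)) {
    M[fi[r], ti[r]] <- max(M[fi[r], ti[r]], ed$weight[r])
    M[ti[r], fi[r]] <- max(M[ti[r], fi[r]], ed$weight[r])
  }
  loop <- apply(M, 1, max)
  loop[loop == 0] <- 1
  diag(M) <- loop
  normalize <- function(A) sweep(A, 2, colSums(A), "/")
  M <- normalize(M)
  it <- 0L
  repeat {
    it <- it + 1L
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol || it >= max_iter) break
  }
  sup <- (M > 0) | (t(M) > 0)
  g <- igraph::graph_from_adjacency_matrix(sup, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  clusters <- split(ids, comp)
  names(clusters) <- NULL
  list(clusters = clusters, inflation = inflation, iterations = it)
}
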