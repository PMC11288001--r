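# phylogeny: core-gene concatenation phylogenomics.  Per-gene center-star
# MSA (global pairwise alignments merged by "once a gap, always a gap"),
# gap-column trimming, fixed-order concatenation, pairwise-deletion
# p-distance, neighbor joining, and column bootstrap.

#' Canonical core-gene set and concatenation order
#' @export
core_gene_names <- function() {
  c("portal", "TerL", "capsid", "PDDEXK", "AAA_ATPase", "PrimPol")
}

#' Center-star multiple sequence alignment
#'
#' The center is the sequence with the maximum summed global-alignment
#' score to all others; every other sequence is aligned to the center
#' pairwise and the alignments are merged under "once a gap, always a
#' gap".
#'
#' @param seqs named character vector of >= 2 protein sequences.
#' @param gene optional gene name attached to the result.
#' @return an `msa` list: `gene`, `rows` (named aligned strings, equal
#'   length), `ncol`.
#' @export
center_star_msa <- function(seqs, gene = "gene") {
  n <- length(seqs)
  if (n < 2) stop("center-star MSA needs at least two sequences")
  ids <- names(seqs)
  if (n == 2) {
    al <- global_protein(setNames(seqs[1], ids[1]), setNames(seqs[2], ids[2]))
    rows <- cigar_to_rows(seqs[[1]], seqs[[2]], al$cigar)
    return(structure(list(gene = gene,
                          rows = setNames(rows, ids),
                          ncol = nchar(rows[1])), class = "msa"))
  }
  tot <- vapply(seq_len(n), function(i)
    sum(vapply(seq_len(n)[-i], function(j)
      protein_score(seqs[[i]], seqs[[j]], local = FALSE), numeric(1))),
    numeric(1))
  ci <- which.max(tot)
  center <- seqs[[ci]]
  Lc <- nchar(center)
  others <- setdiff(seq_len(n), ci)
  # per aligned row: residue at each center position (or "-") and
  # insertion strings after center position p (p in 0..Lc)
  rowchar <- list(); rowins <- list()
  ins_len <- integer(Lc + 1)
  for (oi in others) {
    al <- global_protein(setNames(center, "c"), setNames(seqs[[oi]], "o"))
    ops <- chars(expand_cigar(al$cigar))
    rc <- character(Lc)
    ri <- vector("list", Lc + 1)
    p <- 0L; sp <- 0L
    for (op in ops) {
      if (op == "M") { p <- p + 1L; sp <- sp + 1L; rc[p] <- substr(seqs[[oi]], sp, sp) }
      else if (op == "I") { p <- p + 1L; rc[p] <- "-" }   # center residue vs gap
      else { sp <- sp + 1L; ri[[p + 1L]] <- c(ri[[p + 1L]], substr(seqs[[oi]], sp, sp)) }
    }
    id <- ids[oi]
    rowchar[[id]] <- rc
    rowins[[id]] <- ri
    ins_len <- pmax(ins_len, vapply(ri, length, integer(1)))
  }
  build_row <- function(rc, ri) {
    parts <- character(0)
    for (p in 0:Lc) {
      if (ins_len[p + 1] > 0) {
        blk <- ri[[p + 1]]
        parts <- c(parts, blk, rep("-", ins_len[p + 1] - length(blk)))
      }
      if (p < Lc) parts <- c(parts, rc[p + 1])
    }
    paste(parts, collapse = "")
  }
  rows <- setNames(character(n), ids)
  rows[ids[ci]] <- build_row(chars(center), vector("list", Lc + 1))
  for (id in names(rowchar)) rows[id] <- build_row(rowchar[[id]], rowins[[id]])
  structure(list(gene = gene, rows = rows, ncol = nchar(rows[[1]])),
            class = "msa")
}

expand_cigar <- function(cigar) {
  m <- gregexpr("[0-9]+[MID]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MID]", cigar))[[1]]
  paste(unlist(lapply(toks, function(t) {
    k <- as.integer(sub("[MID]", "", t))
    strrep(substr(t, nchar(t), nchar(t)), k)
  })), collapse = "")
}

# two aligned rows from a global cigar (query row, subject row)
cigar_to_rows <- function(q, s, cigar) {
  ops <- chars(expand_cigar(cigar))
  qi <- si <- 0L
  qa <- sa <- character(length(ops))
  for (k in seq_along(ops)) {
    op <- ops[k]
    if (op != "D") { qi <- qi + 1L; qa[k] <- substr(q, qi, qi) } else qa[k] <- "-"
    if (op != "I") { si <- si + 1L; sa[k] <- substr(s, si, si) } else sa[k] <- "-"
  }
  c(paste(qa, collapse = ""), paste(sa, collapse = ""))
}

#' Trim gap-rich columns and concatenate gene alignments
#'
#' Genomes present in fewer than `min_genes_shared` of the input MSAs are
#' excluded (with a warning); absent genes are filled with all-gap rows;
#' columns with a gap fraction strictly above `gap_frac_max` are removed
#' per gene; genes are concatenated in the declared fixed order
#' ([core_gene_names()] first, others alphabetically).
#'
#' @param msas named list of `msa` objects (names = gene names; row names
#'   = genome ids).
#' @param gap_frac_max column gap-fraction threshold (default 0.5).
#' @param min_genes_shared minimum genes a genome must have (default 4).
#' @return `msa` with an extra `partitions` data.frame (gene, start, end;
#'   1-based inclusive on the concatenated alignment).
#' @export
trim_and_concat <- function(msas, gap_frac_max = 0.5, min_genes_shared = 4) {
  ord <- c(intersect(core_gene_names(), names(msas)),
           sort(setdiff(names(msas), core_gene_names())))
  msas <- msas[ord]
  genomes <- sort(unique(unlist(lapply(msas, function(m) names(m$rows)))))
  presence <- vapply(genomes, function(g)
    sum(vapply(msas, function(m) g %in% names(m$rows), logical(1))),
    integer(1))
  drop <- genomes[presence < min_genes_shared]
  if (length(drop) > 0)
    warning("excluded (fewer than ", min_genes_shared, " core genes): ",
            paste(drop, collapse = ", "))
  genomes <- setdiff(genomes, drop)
  if (length(genomes) == 0) stop("no genomes left after gene-count filter")
  pieces <- character(length(genomes)); names(pieces) <- genomes
  parts <- list(); at <- 0L
  for (g in names(msas)) {
    m <- msas[[g]]
    mat <- matrix("-", length(genomes), m$ncol,
                  dimnames = list(genomes, NULL))
    have <- intersect(names(m$rows), genomes)
    for (id in have) mat[id, ] <- chars(m$rows[[id]])
    gapfrac <- colMeans(mat == "-")
    mat <- mat[, gapfrac <= gap_frac_max, drop = FALSE]
    if (ncol(mat) == 0) next
    pieces <- setNames(paste0(pieces, apply(mat, 1, paste, collapse = "")),
                       genomes)
    parts[[g]] <- data.frame(gene = g, start = at + 1L,
                             end = at + ncol(mat), stringsAsFactors = FALSE)
    at <- at + ncol(mat)
  }
  structure(list(gene = "concatenated", rows = pieces, ncol = at,
                 partitions = do.call(rbind, parts)), class = "msa")
}

#' Pairwise-deletion p-distance matrix of an alignment
#'
#' For each pair, only columns where both rows are non-gap are compared;
#' `d = 1 - matches / comparable`.  Fewer than 10 comparable columns for
#' a pair is an error naming the pair.
#'
#' @param msa an `msa` object.
#' @export
p_distance <- function(msa) {
  ids <- names(msa$rows)
  mat <- do.call(rbind, strsplit(unname(msa$rows), "", fixed = TRUE))
  rownames(mat) <- ids
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  nongap <- mat != "-"
  for (a in seq_len(n)) for (b in seq_len(a - 1L)) {
    both <- nongap[a, ] & nongap[b, ]
    nc <- sum(both)
    if (nc < 10)
      stop("fewer than 10 comparable columns between ", ids[a], " and ", ids[b])
    d <- 1 - sum(mat[a, both] == mat[b, both]) / nc
    D[a, b] <- D[b, a] <- d
  }
  D
}

#' Neighbor joining from a distance matrix
#'
#' Canonical NJ (Saitou-Nei, Studier-Keppler Q-matrix) on a symmetric
#' distance matrix; recovers the generating topology exactly for
#' additive distances.
#'
#' @param D symmetric distance matrix with dimnames.
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_from_distances <- function(D) {
  ape::nj(stats::as.dist(D))
}

#' Neighbor-joining tree with column bootstrap
#'
#' Canonical NJ (Saitou-Nei with the Studier-Keppler Q-matrix, via
#' \pkg{ape}) on the pairwise-deletion p-distance of the alignment.
#' Negative branch lengths are clamped to zero.  Supports are bipartition
#' frequencies (x100) over `bootstrap_n` column-resampled replicates and
#' are stored in `node.label`.
#'
#' @param msa an `msa` object with >= 4 rows.
#' @param bootstrap_n bootstrap replicates (0 to skip).
#' @param seed integer seed for the column resampling.
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(msa, bootstrap_n = 100, seed = 1) {
  if (length(msa$rows) < 4) stop("need >= 4 sequences for an unrooted tree")
  D <- p_distance(msa)
  tree <- ape::nj(as.dist(D))
  tree$edge.length[tree$edge.length < 0] <- 0
  if (bootstrap_n > 0) {
    mat <- do.call(rbind, strsplit(unname(msa$rows), "", fixed = TRUE))
    rownames(mat) <- names(msa$rows)
    boots <- with_seed(seed, lapply(seq_len(bootstrap_n), function(r) {
      cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      sub <- mat[, cols, drop = FALSE]
      rows <- setNames(apply(sub, 1, paste, collapse = ""), rownames(mat))
      bt <- ape::nj(as.dist(p_distance(list(rows = rows))))
      bt
    }))
    cnt <- ape::prop.clades(tree, boots, rooted = FALSE)
    cnt[is.na(cnt)] <- 0
    tree$node.label <- as.character(round(100 * cnt / bootstrap_n))
  }
  tree
}

#' Bootstrap support of the bipartition separating a tip set
#'
#' Returns the support value (0-100) at the internal edge whose
#' bipartition splits `tips` from the rest, or `NA` when the tree does
#' not contain that split.
#'
#' @param tree a tree from [nj_tree()] (supports in `node.label`).
#' @param tips character vector of tip labels.
#' @export
split_support <- function(tree, tips) {
  all_tips <- tree$tip.label
  if (!all(tips %in% all_tips)) stop("unknown tip label")
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  want <- sort(match(tips, labs))
  comp <- sort(setdiff(seq_along(labs), want))
  for (k in seq_along(pp)) {
    s <- sort(pp[[k]])
    if (identical(s, want) || identical(s, comp)) {
      node <- length(all_tips) + k
      if (is.null(tree$node.label)) return(NA_real_)
      return(as.numeric(tree$node.label[node - length(all_tips)]))
    }
  }
  NA_real_
}

#' Does the tree contain the bipartition separating `tips`?
#' @inheritParams split_support
#' @export
has_split <- function(tree, tips) {
  if (length(tips) <= 1 || length(tips) >= length(tree$tip.label) - 1)
    return(TRUE)  # trivial splits always present
  !is.na(split_support_node(tree, tips))
}

split_support_node <- function(tree, tips) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  want <- sort(match(tips, labs))
  comp <- sort(setdiff(seq_along(labs), want))
  for (k in seq_along(pp)) {
    s <- sort(pp[[k]])
    if (identical(s, want) || identical(s, comp)) return(k)
  }
  NA_integer_
}
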