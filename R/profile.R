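# profile: position-specific scoring models built from hallmark-gene
# seed alignments, and family-member retrieval with the standard filter
# cascade (e-value, bitscore, identity vs nearest seed, profile
# coverage).  The PSSM + affine-gap local alignment is a deliberately
# small approximation of a profile-HMM search with the same threshold
# semantics.

#' Build a log-odds PSSM from a seed alignment
#'
#' Match columns are alignment columns with at most 50% gaps.  Per-column
#' scores are log2 odds of the smoothed observed frequencies over the
#' BLOSUM62 marginal background: one unit pseudocount distributed
#' proportionally to the background, so every unobserved residue scores
#' `log2(1 / (n_obs + 1))`.
#'
#' @param seed_msa named character vector of aligned protein sequences
#'   (equal lengths, `-` gaps), e.g. from [read_protein_fasta()] with
#'   `gaps = TRUE`.
#' @param name profile name (e.g. `"TerL"`).
#' @return a `profile_model` list: `name`, `scores` (match-columns x 20
#'   log2-odds matrix), `length`, `seed_ids`, `seeds` (ungapped seed
#'   sequences), `background`.
#' @export
build_profile <- function(seed_msa, name = "profile") {
  if (length(seed_msa) < 2) stop("profile undefined for a single seed")
  L <- unique(nchar(seed_msa))
  if (length(L) != 1) stop("seed alignment rows have unequal lengths")
  aas <- names(AA_BACKGROUND)
  m <- do.call(rbind, strsplit(seed_msa, "", fixed = TRUE))
  gap_frac <- colMeans(m == "-")
  keep <- which(gap_frac <= 0.5)
  if (length(keep) == 0) stop("no match columns in seed alignment")
  scores <- matrix(0, length(keep), 20, dimnames = list(NULL, aas))
  for (ci in seq_along(keep)) {
    col <- m[, keep[ci]]
    col <- col[col != "-"]
    cnt <- table(factor(col, levels = aas))
    p <- (as.numeric(cnt) + AA_BACKGROUND) / (length(col) + 1)
    scores[ci, ] <- log2(p / AA_BACKGROUND)
  }
  structure(list(name = name, scores = scores, length = length(keep),
                 seed_ids = names(seed_msa),
                 seeds = setNames(gsub("-", "", seed_msa, fixed = TRUE),
                                  names(seed_msa)),
                 background = AA_BACKGROUND),
            class = "profile_model")
}

# PSSM in half-bit units over the full DP alphabet (non-standard letters
# scored 0), commensurate with BLOSUM62 integer scores and the shared
# gap penalties / bit-score mapping.
pssm_dp_matrix <- function(model) {
  alph <- aa_alphabet()
  m <- matrix(0, model$length, length(alph), dimnames = list(NULL, alph))
  m[, colnames(model$scores)] <- 2 * model$scores
  m
}

#' Search proteins with a profile
#'
#' Each protein is locally aligned to the PSSM under affine gaps
#' (open 11, extend 1 by default).  A hit must pass all four gates:
#' e-value, bit-like score, identity against the nearest (highest
#' scoring) seed, and profile coverage (aligned profile columns over
#' profile length).
#'
#' @param model from [build_profile()].
#' @param proteins gene-call data.frame (columns `orf_id`, `genome_id`,
#'   `protein`) or a named character vector.
#' @param e_max,bits_min,id_min,cov_min the filter cascade
#'   (defaults 1e-3, 50, 0.25, 0.80).
#' @param gap_open,gap_extend gap penalties.
#' @return data.frame of passing hits sorted by score: `genome_id`,
#'   `orf_id`, `profile`, `bits`, `best_seed_identity`, `coverage`,
#'   `evalue`.
#' @export
search_profile <- function(model, proteins, e_max = 1e-3, bits_min = 50,
                           id_min = 0.25, cov_min = 0.80,
                           gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(model, "profile_model"))
  if (is.data.frame(proteins)) {
    prot <- setNames(proteins$protein, proteins$orf_id)
    gid <- setNames(proteins$genome_id, proteins$orf_id)
  } else {
    prot <- proteins
    gid <- setNames(rep(NA_character_, length(prot)), names(prot))
  }
  if (length(prot) == 0) return(empty_hallmark_hits())
  pm <- pssm_dp_matrix(model)
  alph <- colnames(pm)
  nsub <- length(prot)
  rows <- list()
  for (i in seq_along(prot)) {
    al <- cpp_pssm_align(pm, aa_encode(prot[[i]], alph), gap_open, gap_extend)
    bits <- bit_score(al$score)
    cov <- al$prof_cols / model$length
    ev <- ka_evalue(al$score, model$length, nchar(prot[[i]]), nsub)
    if (bits < bits_min || cov < cov_min || ev > e_max) next
    # identity against the nearest seed
    seed_sc <- vapply(model$seeds, function(sd)
      protein_score(prot[[i]], sd), numeric(1))
    best_seed <- model$seeds[[which.max(seed_sc)]]
    ident <- local_protein(prot[[i]], best_seed)$identity
    if (ident < id_min) next
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = unname(gid[names(prot)[i]]), orf_id = names(prot)[i],
      profile = model$name, bits = bits, best_seed_identity = ident,
      coverage = cov, evalue = ev, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty_hallmark_hits())
  res <- do.call(rbind, rows)
  res[order(-res$bits, res$orf_id), , drop = FALSE]
}

empty_hallmark_hits <- function() {
  data.frame(genome_id = character(0), orf_id = character(0),
             profile = character(0), bits = numeric(0),
             best_seed_identity = numeric(0), coverage = numeric(0),
             evalue = numeric(0), stringsAsFactors = FALSE)
}

#' Retrieve candidate family contigs with hallmark profiles
#'
#' A contig is retained when at least one profile yields a passing hit
#' among its called proteins.
#'
#' @param contigs genome table.
#' @param models list of `profile_model`s (e.g. TerL, capsid, Prim-Pol).
#' @param calls optional precomputed gene calls ([call_orfs_all()]);
#'   computed here otherwise.
#' @param ... gates passed to [search_profile()].
#' @return list: `retained` (contig ids), `hits` (per-contig hit table).
#' @export
retrieve_candidates <- function(contigs, models, calls = NULL, ...) {
  if (is.null(calls)) calls <- call_orfs_all(contigs)
  hits <- do.call(rbind, lapply(models, search_profile, proteins = calls, ...))
  rownames(hits) <- NULL
  list(retained = sort(unique(hits$genome_id)), hits = hits)
}
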