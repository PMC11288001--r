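# align: pairwise alignment engine.  Protein local (Smith-Waterman) and
# global (Needleman-Wunsch) alignment under affine gaps, and a
# seed-and-extend nucleotide search.  "Identity" and "coverage" are
# defined here once, BLAST-report style:
#   identity = matching columns / all alignment columns (gaps included)
#   q_cov / s_cov = aligned (non-gap) residues of that sequence / its length
# Gap model: a gap of length L costs gap_open + L * gap_extend.

AA_BACKGROUND <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025, Q = 0.034,
  E = 0.054, G = 0.074, H = 0.026, I = 0.068, L = 0.099, K = 0.058,
  M = 0.025, F = 0.047, P = 0.039, S = 0.057, T = 0.051, W = 0.013,
  Y = 0.032, V = 0.073)

# Karlin-Altschul ungapped BLOSUM62 constants, used only so that raw
# scores can be expressed on a bit-like scale for thresholding parity
# with published "bitscore >= 50" style gates.
KA_LAMBDA <- 0.318
KA_K <- 0.13

.align_env <- new.env(parent = emptyenv())

#' Protein scoring matrix
#'
#' BLOSUM matrices (from Biostrings) with the unknown residue X scored 0
#' against everything.
#'
#' @param name "BLOSUM62" (default) or "BLOSUM50".
#' @return numeric matrix with dimnames over the 24-letter alphabet.
#' @export
aa_matrix <- function(name = "BLOSUM62") {
  name <- match.arg(name, c("BLOSUM62", "BLOSUM50"))
  key <- paste0("mat_", name)
  if (is.null(.align_env[[key]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    m <- as.matrix(e[[name]])
    m["X", ] <- 0
    m[, "X"] <- 0
    .align_env[[key]] <- m
  }
  .align_env[[key]]
}

aa_alphabet <- function() rownames(aa_matrix())

aa_encode <- function(s, alphabet = aa_alphabet()) {
  v <- match(chars(s), alphabet) - 1L
  if (anyNA(v)) stop("invalid amino-acid residue in sequence")
  v
}

#' Bit-like score and crude e-value
#'
#' `bit_score` maps a raw alignment score to (lambda * S - ln K) / ln 2
#' with fixed published ungapped BLOSUM62 constants.  `ka_evalue` is the
#' corresponding Karlin-Altschul e-value with search space
#' `|q| * |s| * n_subjects`; both are approximations used only for the
#' e-value/bitscore filter gates.
#'
#' @param score raw alignment score.
#' @export
bit_score <- function(score) (KA_LAMBDA * score - log(KA_K)) / log(2)

#' @rdname bit_score
#' @param qlen,slen,n_subjects search-space dimensions.
#' @export
ka_evalue <- function(score, qlen, slen, n_subjects = 1) {
  as.numeric(qlen) * as.numeric(slen) * n_subjects * 2^(-bit_score(score))
}

align_result <- function(query_id, subject_id, qlen, slen, raw, n_subjects = 1) {
  cols <- raw$aligned_cols
  data.frame(
    query_id = query_id, subject_id = subject_id,
    score = raw$score, bits = bit_score(raw$score),
    identity = if (cols > 0) raw$matches / cols else 0,
    matches = raw$matches, aligned_cols = cols,
    q_cov = raw$q_aligned / qlen, s_cov = raw$s_aligned / slen,
    qstart = raw$qstart, qend = raw$qend,
    sstart = raw$sstart, send = raw$send,
    gapopens = raw$gapopens,
    evalue = ka_evalue(raw$score, qlen, slen, n_subjects),
    cigar = raw$cigar, stringsAsFactors = FALSE)
}

#' Pairwise protein alignment
#'
#' `local_protein` is optimal local (Smith-Waterman) and `global_protein`
#' optimal global (Needleman-Wunsch) alignment under affine gaps.
#'
#' @param q,s amino-acid strings (X allowed, scored 0), or named length-1
#'   vectors whose names become query/subject ids.
#' @param matrix scoring matrix name, see [aa_matrix()].
#' @param gap_open,gap_extend affine gap parameters; a gap of length L
#'   costs `gap_open + L * gap_extend`.  Use `gap_open = 0` for linear gaps.
#' @param n_subjects search-space multiplier for the reported e-value.
#' @return one-row data.frame: ids, raw `score`, `bits`, `identity`
#'   (matches over all alignment columns), `q_cov`/`s_cov`, 1-based
#'   aligned coordinates, `evalue`, `cigar`.
#' @export
local_protein <- function(q, s, matrix = "BLOSUM62", gap_open = 11,
                          gap_extend = 1, n_subjects = 1) {
  protein_align(q, s, matrix, gap_open, gap_extend, TRUE, n_subjects)
}

#' @rdname local_protein
#' @export
global_protein <- function(q, s, matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, n_subjects = 1) {
  protein_align(q, s, matrix, gap_open, gap_extend, FALSE, n_subjects)
}

protein_align <- function(q, s, matrix, gap_open, gap_extend, local,
                          n_subjects = 1) {
  qid <- names(q) %||% "query"; sid <- names(s) %||% "subject"
  q <- unname(q); s <- unname(s)
  if (!nzchar(q) || !nzchar(s)) stop("empty sequence")
  m <- aa_matrix(matrix)
  raw <- cpp_pair_align(aa_encode(q, rownames(m)), aa_encode(s, rownames(m)),
                        m, gap_open, gap_extend, local)
  align_result(qid, sid, nchar(q), nchar(s), raw, n_subjects)
}

#' Raw pairwise protein alignment score (score only)
#'
#' Faster than [local_protein()]/[global_protein()] when only the
#' optimal score is needed (no traceback).
#'
#' @inheritParams local_protein
#' @param local TRUE for Smith-Waterman, FALSE for Needleman-Wunsch.
#' @export
protein_score <- function(q, s, matrix = "BLOSUM62", gap_open = 11,
                          gap_extend = 1, local = TRUE) {
  m <- aa_matrix(matrix)
  cpp_align_score(aa_encode(q, rownames(m)), aa_encode(s, rownames(m)),
                  m, gap_open, gap_extend, local)
}

# ungapped match vector between q[qi..] and s[si..] over len positions
match_vector <- function(q, s, qi, si, len) {
  a <- charToRaw(substr(q, qi, qi + len - 1))
  b <- charToRaw(substr(s, si, si + len - 1))
  as.integer(a == b)
}

#' Nucleotide seed-and-extend search
#'
#' BLASTn-like search: exact shared k-mers anchor diagonals on both
#' strands; each anchored diagonal is scanned for all maximal-scoring
#' ungapped segments (match/mismatch scoring), and segments are reported
#' greedily non-overlapping in query coordinates.  Suited to
#' high-identity comparisons (dereplication, read recruitment, prophage
#' search); no gapped extension is attempted.
#'
#' @param q,s nucleotide strings (named length-1 vectors give ids).
#' @param k seed length (error if `k` exceeds either sequence).
#' @param match,mismatch segment scoring (mismatch must be negative).
#' @param min_score minimum reported segment score; defaults to `2 * k`.
#' @param max_diagonals cap on anchored diagonals examined, densest first.
#' @param cache optional environment reusing k-mer tables across calls
#'   (keyed by sequence id and strand; ids must then be stable).
#' @return data.frame of segments sorted by score (desc) then
#'   coordinates: ids, score, identity, aligned_cols, q_cov, s_cov,
#'   1-based qstart/qend/sstart/send (subject coordinates always on the
#'   forward strand of `s`), strand, evalue.
#' @export
nt_seed_extend <- function(q, s, k = 15, match = 1, mismatch = -2,
                           min_score = NULL, max_diagonals = 10000,
                           cache = NULL) {
  qid <- names(q) %||% "query"; sid <- names(s) %||% "subject"
  q <- unname(q); s <- unname(s)
  nq <- nchar(q); ns <- nchar(s)
  if (k > min(nq, ns)) stop("k exceeds sequence length")
  stopifnot(mismatch < 0)
  if (is.null(min_score)) min_score <- 2 * k
  out <- list()
  for (strand in c("+", "-")) {
    s2 <- if (strand == "+") s else revcomp(s)
    qt <- cached_kmer_table(cache, qid, "+", q, k)
    st <- cached_kmer_table(cache, sid, strand, s2, k)
    segs <- diagonal_segments(q, s2, k, match, mismatch, min_score,
                              max_diagonals, qt = qt, st = st)
    if (nrow(segs) == 0) next
    if (strand == "-") {
      tmp <- segs$sstart
      segs$sstart <- ns - segs$send + 1L
      segs$send <- ns - tmp + 1L
    }
    segs$strand <- strand
    out[[strand]] <- segs
  }
  if (length(out) == 0) return(empty_nt_hits(qid, sid))
  segs <- do.call(rbind, out)
  segs <- segs[order(-segs$score, segs$qstart, segs$sstart, segs$strand), ,
               drop = FALSE]
  # greedy near-non-overlap in query coordinates (a small overlap of up
  # to 10% of the shorter segment is tolerated so that e.g. circularly
  # permuted copies sharing a short repeat keep both segments)
  keep <- logical(nrow(segs))
  taken_s <- taken_e <- integer(0)
  for (i in seq_len(nrow(segs))) {
    ov <- pmin(segs$qend[i], taken_e) - pmax(segs$qstart[i], taken_s) + 1L
    len_i <- segs$qend[i] - segs$qstart[i] + 1L
    lim <- 0.1 * pmin(len_i, taken_e - taken_s + 1L)
    if (!any(ov > lim)) {
      keep[i] <- TRUE
      taken_s <- c(taken_s, segs$qstart[i])
      taken_e <- c(taken_e, segs$qend[i])
    }
  }
  segs <- segs[keep, , drop = FALSE]
  len <- segs$qend - segs$qstart + 1L
  data.frame(
    query_id = qid, subject_id = sid, score = segs$score,
    identity = segs$matches / len, matches = segs$matches,
    aligned_cols = len, q_cov = len / nq, s_cov = len / ns,
    qstart = segs$qstart, qend = segs$qend,
    sstart = segs$sstart, send = segs$send, strand = segs$strand,
    evalue = ka_evalue(segs$score, nq, ns), row.names = NULL,
    stringsAsFactors = FALSE)
}

empty_nt_hits <- function(qid, sid) {
  data.frame(query_id = character(0), subject_id = character(0),
             score = numeric(0), identity = numeric(0), matches = integer(0),
             aligned_cols = integer(0), q_cov = numeric(0), s_cov = numeric(0),
             qstart = integer(0), qend = integer(0), sstart = integer(0),
             send = integer(0), strand = character(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

# shared-kmer diagonals between q and s (forward orientation of both),
# returning maximal-scoring ungapped segments per anchored diagonal.
# Seeds from k-mers repeated more than max_occ times in either sequence
# are masked (repeat seeds anchor no informative diagonal).
diagonal_segments <- function(q, s, k, match, mismatch, min_score,
                              max_diagonals, max_occ = 10,
                              qt = NULL, st = NULL) {
  nq <- nchar(q); ns <- nchar(s)
  if (is.null(qt)) qt <- nt_kmer_table(q, k, max_occ)
  if (is.null(st)) st <- nt_kmer_table(s, k, max_occ)
  data.table::setnames(qt, c("kmer", "qpos"))
  data.table::setnames(st, c("kmer", "spos"))
  hits <- merge(qt, st, by = "kmer", allow.cartesian = TRUE)
  none <- data.frame(qstart = integer(0), qend = integer(0),
                     sstart = integer(0), send = integer(0),
                     score = numeric(0), matches = integer(0))
  if (nrow(hits) == 0) return(none)
  hits$diag <- hits$qpos - hits$spos
  # scan each anchored diagonal only around its supporting seeds
  margin <- 2000L
  dran <- hits[, .(n = .N, lo = min(qpos), hi = max(qpos)), by = diag]
  dran <- dran[order(-n)]
  if (nrow(dran) > max_diagonals) dran <- dran[seq_len(max_diagonals)]
  res <- list()
  for (r in seq_len(nrow(dran))) {
    d <- dran$diag[r]
    qi0 <- max(1L, 1L + d)
    qhi0 <- min(nq, ns + d)
    qi <- max(qi0, dran$lo[r] - margin)
    qe <- min(qhi0, dran$hi[r] + k - 1L + margin)
    len <- qe - qi + 1L
    if (len < k) next
    si <- qi - d
    mv <- match_vector(q, s, qi, si, len)
    segs <- cpp_max_segments(mv, match, mismatch, min_score)
    if (nrow(segs) == 0) next
    res[[as.character(d)]] <- data.frame(
      qstart = qi + as.integer(segs[, "start"]) - 1L,
      qend = qi + as.integer(segs[, "end"]) - 1L,
      sstart = si + as.integer(segs[, "start"]) - 1L,
      send = si + as.integer(segs[, "end"]) - 1L,
      score = segs[, "score"], matches = as.integer(segs[, "matches"]))
  }
  if (length(res) == 0) return(none)
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

# repeat-masked k-mer position table of one sequence; k-mers are 2-bit
# packed numeric codes (exact for k <= 26), k-mers containing N dropped
nt_kmer_table <- function(s, k, max_occ = 10) {
  n <- nchar(s)
  lut <- rep(NA_real_, 256)
  lut[as.integer(charToRaw("ACGT")) + 1L] <- 0:3
  b <- lut[as.integer(charToRaw(s)) + 1L]
  m <- n - k + 1L
  codes <- numeric(m)
  for (j in 0:(k - 1L)) codes <- codes * 4 + b[(1L + j):(m + j)]
  t <- data.table::data.table(kmer = codes, pos = seq_len(m))
  t <- t[!is.na(kmer)]
  t <- t[, if (.N <= max_occ) .SD, by = kmer]
  if (ncol(t) < 2)  # all k-mers masked
    t <- data.table::data.table(kmer = numeric(0), pos = integer(0))
  t
}

cached_kmer_table <- function(cache, id, strand, seq, k, max_occ = 10) {
  if (is.null(cache)) return(NULL)
  key <- paste(id, strand, k, sep = "\r")
  if (is.null(cache[[key]])) cache[[key]] <- nt_kmer_table(seq, k, max_occ)
  data.table::copy(cache[[key]])
}

#' BLAST outfmt-6 style table from alignment results
#'
#' @param hits data.frame from the aligners.
#' @return data.frame with the 12 canonical columns (1-based coordinates,
#'   pident as percent).
#' @export
blast_table <- function(hits) {
  qal <- hits$qend - hits$qstart + 1L
  sal <- abs(hits$send - hits$sstart) + 1L
  data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = round(100 * hits$identity, 2), length = hits$aligned_cols,
    mismatch = (qal + sal - hits$aligned_cols) - hits$matches,
    gapopen = hits$gapopens %||% 0L,
    qstart = hits$qstart, qend = hits$qend,
    sstart = hits$sstart, send = hits$send,
    evalue = signif(hits$evalue, 3), bitscore = round(bit_score(hits$score), 1),
    stringsAsFactors = FALSE)
}
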