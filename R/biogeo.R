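# biogeo: read recruitment against a dereplicated reference set, RPKM
# abundance matrices, environmental correlation/regression, and the
# high-vs-low G+C Mann-Whitney comparison.

#' Recruit reads to reference genomes
#'
#' Each read is matched to candidate references by shared k-mers and
#' scored by ungapped alignment (the simulator is substitution-only; the
#' thresholds assume high-identity recruitment).  The best alignment per
#' read is kept when it passes all gates: identity >= `id_min`, aligned
#' length >= `aln_min`, aligned length / read length >= `readcov_min`.
#' Ties across references go to the lexicographically smallest reference
#' id; each read counts at most once.
#'
#' @param reads character vector of reads, or a FASTQ path.
#' @param refs genome table (dereplicate with [greedy_derep()] first).
#' @param id_min,aln_min,readcov_min recruitment gates
#'   (defaults 0.95, 50, 0.80).
#' @param k seed k-mer length.
#' @param stride k-mer sampling stride along each read.
#' @return named integer vector of per-reference read counts (attribute
#'   `"n_reads"` = input read count).
#' @export
recruit_reads <- function(reads, refs, id_min = 0.95, aln_min = 50,
                          readcov_min = 0.80, k = 20, stride = 10) {
  if (nrow(refs) == 0) stop("empty reference set")
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_fastq(reads)
  counts <- setNames(integer(nrow(refs)), refs$id)
  n_reads <- length(reads)
  if (n_reads == 0) return(structure(counts, n_reads = 0L))
  idx <- ref_kmer_index(refs, k)
  best <- best_read_hits(reads, refs, idx, k, stride)
  if (!is.null(best)) {
    rl <- nchar(reads)[best$read]
    keep <- best$identity >= id_min & best$alen >= aln_min &
      best$alen / rl >= readcov_min
    if (any(keep)) {
      tab <- table(best$ref[keep])
      counts[names(tab)] <- as.integer(tab)
    }
  }
  structure(counts, n_reads = n_reads)
}

ref_kmer_index <- function(refs, k) {
  parts <- lapply(seq_len(nrow(refs)), function(i) {
    s <- refs$seq[i]
    L <- nchar(s)
    if (L < k) return(NULL)
    data.table::data.table(kmer = substring(s, 1:(L - k + 1), k:L),
                           ref = refs$id[i], spos = 1:(L - k + 1))
  })
  data.table::rbindlist(parts)
}

# best candidate alignment per read over both strands
best_read_hits <- function(reads, refs, idx, k, stride) {
  refseq <- setNames(refs$seq, refs$id)
  reflen <- setNames(refs$length_bp, refs$id)
  cands <- list()
  for (strand in c("+", "-")) {
    rr <- if (strand == "+") reads else revcomp(reads)
    rl <- nchar(rr)
    offs <- lapply(rl, function(L) unique(c(seq(1L, L - k + 1L, by = stride),
                                            L - k + 1L)))
    qt <- data.table::data.table(
      read = rep(seq_along(rr), lengths(offs)),
      qpos = unlist(offs))
    qt[, kmer := substring(rr[read], qpos, qpos + k - 1L)]
    hit <- merge(qt, idx, by = "kmer", allow.cartesian = TRUE)
    if (nrow(hit) == 0) next
    hit[, diag := spos - qpos]
    hit <- unique(hit[, .(read, ref, diag)])
    # ungapped alignment of the read against the ref window on this diagonal
    rlh <- nchar(rr)[hit$read]
    qs <- pmax(1L, 1L - hit$diag)
    qe <- pmin(rlh, reflen[hit$ref] - hit$diag)
    ok <- qe - qs + 1L >= k
    hit <- hit[ok]; qs <- qs[ok]; qe <- qe[ok]
    if (nrow(hit) == 0) next
    alen <- qe - qs + 1L
    rpart <- substring(rr[hit$read], qs, qe)
    wpart <- substring(refseq[hit$ref], qs + hit$diag, qe + hit$diag)
    matches <- count_matches(rpart, wpart)
    cands[[strand]] <- data.table::data.table(
      read = hit$read, ref = hit$ref, alen = alen, matches = matches,
      identity = matches / alen)
  }
  if (length(cands) == 0) return(NULL)
  d <- data.table::rbindlist(cands)
  d <- d[order(read, -matches, ref)]
  d[!duplicated(read)]
}

# Best ungapped segment per read against one genome (both strands),
# k-mer anchored.  qstart/qend are on the ORIGINAL read orientation;
# sstart/send on the forward genome.  Shared by junction detection.
map_read_segments <- function(reads, genome_seq, k = 15, stride = 5,
                              match = 1, mismatch = -2) {
  if (length(reads) == 0) return(NULL)
  gl <- nchar(genome_seq)
  gidx <- data.table::data.table(
    kmer = substring(genome_seq, 1:(gl - k + 1), k:gl),
    spos = 1:(gl - k + 1))
  best <- NULL
  for (strand in c("+", "-")) {
    rr <- if (strand == "+") reads else revcomp(reads)
    rl <- nchar(rr)
    offs <- lapply(rl, function(L) unique(c(seq(1L, L - k + 1L, by = stride),
                                            L - k + 1L)))
    qt <- data.table::data.table(read = rep(seq_along(rr), lengths(offs)),
                                 qpos = unlist(offs))
    qt[, kmer := substring(rr[read], qpos, qpos + k - 1L)]
    hit <- merge(qt, gidx, by = "kmer", allow.cartesian = TRUE)
    if (nrow(hit) == 0) next
    hit[, diag := spos - qpos]
    hit <- unique(hit[, .(read, diag)])
    rows <- vector("list", nrow(hit))
    for (r in seq_len(nrow(hit))) {
      rd <- hit$read[r]; d <- hit$diag[r]
      qs <- max(1L, 1L - d); qe <- min(rl[rd], gl - d)
      if (qe - qs + 1L < k) next
      mv <- match_vector(rr[rd], genome_seq, qs, qs + d, qe - qs + 1L)
      segs <- cpp_max_segments(mv, match, mismatch, 2 * k)
      if (nrow(segs) == 0) next
      b <- which.max(segs[, "score"])
      a1 <- qs + as.integer(segs[b, "start"]) - 1L   # on rr orientation
      b1 <- qs + as.integer(segs[b, "end"]) - 1L
      qa <- if (strand == "+") a1 else rl[rd] - b1 + 1L
      qb <- if (strand == "+") b1 else rl[rd] - a1 + 1L
      rows[[r]] <- data.frame(
        read = rd, qstart = qa, qend = qb,
        sstart = a1 + d, send = b1 + d, strand = strand,
        score = segs[b, "score"], matches = as.integer(segs[b, "matches"]),
        identity = segs[b, "matches"] / (b1 - a1 + 1),
        stringsAsFactors = FALSE)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0) next
    best <- rbind(best, do.call(rbind, rows))
  }
  if (is.null(best)) return(NULL)
  best <- best[order(-best$score, best$read), , drop = FALSE]
  best <- best[!duplicated(best$read), , drop = FALSE]
  best[order(best$read), , drop = FALSE]
}

# vectorised per-pair match counts for equal-length string pairs
count_matches <- function(a, b) {
  stopifnot(length(a) == length(b))
  out <- integer(length(a))
  for (w in unique(nchar(a))) {
    sel <- which(nchar(a) == w)
    ma <- matrix(charToRaw(paste(a[sel], collapse = "")), nrow = w)
    mb <- matrix(charToRaw(paste(b[sel], collapse = "")), nrow = w)
    out[sel] <- colSums(ma == mb)
  }
  out
}

#' Recruit several samples into a count matrix
#'
#' @param read_sets named list: sample -> reads (vector or FASTQ path).
#' @inheritParams recruit_reads
#' @return integer matrix genomes x samples; attribute
#'   `"total_recruited"` = per-sample recruited totals.
#' @export
recruit_matrix <- function(read_sets, refs, ...) {
  cols <- lapply(read_sets, recruit_reads, refs = refs, ...)
  m <- do.call(cbind, cols)
  colnames(m) <- names(read_sets)
  structure(m, total_recruited = colSums(m))
}

#' RPKM normalisation
#'
#' `RPKM[g, s] = count[g, s] / ((len_g / 1e3) * (total_s / 1e6))`.  The
#' default denominator is the per-sample total of recruited reads
#' (comparison within the reference set); pass raw library sizes in
#' `totals` to switch.  A zero total yields a zero column with a
#' warning.
#'
#' @param counts genomes x samples count matrix.
#' @param lengths named per-genome lengths in bp.
#' @param totals per-sample totals (default: column sums of `counts`).
#' @return RPKM matrix with attributes `counts`, `totals`, `lengths`.
#' @export
rpkm <- function(counts, lengths, totals = NULL) {
  lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0)) stop("invalid genome length")
  if (is.null(totals)) totals <- colSums(counts)
  if (any(totals == 0)) warning("sample(s) with zero mapped reads: ",
                                paste(colnames(counts)[totals == 0],
                                      collapse = ", "))
  denom <- outer(lengths / 1e3, totals / 1e6)
  out <- counts / denom
  out[, totals == 0] <- 0
  structure(out, counts = counts, totals = totals, lengths = lengths)
}

#' Correlate abundances with environmental covariates
#'
#' Per genome and covariate: Pearson r (two-sided t p-value, or an exact
#' permutation p when n <= 8), Spearman rho, and the OLS slope with its
#' t p-value.  Zero-variance abundance rows yield NA with a reason.
#'
#' @param abund RPKM matrix (genomes x samples).
#' @param meta data.frame with a `sample` column matching `colnames(abund)`.
#' @param vars covariate columns (default latitude, temperature,
#'   salinity).
#' @return long data.frame: genome, variable, r, p_r, rho, slope,
#'   p_slope, p_bh (Benjamini-Hochberg over p_r within variable), note.
#' @export
env_correlate <- function(abund, meta,
                          vars = c("latitude", "temperature", "salinity")) {
  stopifnot(all(colnames(abund) %in% meta$sample))
  meta <- meta[match(colnames(abund), meta$sample), ]
  rows <- list()
  for (v in vars) {
    x <- meta[[v]]
    if (sum(!is.na(x)) < 3) stop("fewer than 3 samples with covariate ", v)
    for (g in rownames(abund)) {
      y <- abund[g, ]
      if (sd(y) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          genome = g, variable = v, r = NA_real_, p_r = NA_real_,
          rho = NA_real_, slope = NA_real_, p_slope = NA_real_,
          note = "zero-variance abundance", stringsAsFactors = FALSE)
        next
      }
      n <- length(y)
      r <- cor(x, y)
      p_r <- if (n <= 8) perm_cor_p(x, y) else
        2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
      rho <- suppressWarnings(cor(x, y, method = "spearman"))
      fit <- lm(y ~ x)
      sm <- suppressWarnings(summary(fit))$coefficients  # exact fits warn
      rows[[length(rows) + 1L]] <- data.frame(
        genome = g, variable = v, r = r, p_r = p_r, rho = rho,
        slope = sm[2, 1], p_slope = sm[2, 4], note = "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  for (v in vars) {
    sel <- out$variable == v & !is.na(out$p_r)
    out$p_bh[sel] <- stats::p.adjust(out$p_r[sel], method = "BH")
  }
  out
}

# exact permutation p for the Pearson correlation (n <= 8)
perm_cor_p <- function(x, y) {
  perms <- all_permutations(length(x))
  r_obs <- abs(cor(x, y))
  rs <- apply(perms, 1, function(p) abs(cor(x, y[p])))
  mean(rs >= r_obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Mann-Whitney U test (exact for small groups)
#'
#' Two-sided Mann-Whitney U.  When both groups have <= `exact_max`
#' observations the p-value is computed by full enumeration of group
#' labelings (ties handled by midranks); otherwise the normal
#' approximation with tie correction is used.
#'
#' @param x,y numeric vectors.
#' @param exact_max exact-enumeration size limit per group (default 8).
#' @return list: `u` (U of the first group), `p` (two-sided), `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- combn(n1 + n2, n1)
    us <- apply(combs, 2, function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2)
    p <- 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9))
    p <- min(1, p)
    list(u = u, p = p, method = "exact enumeration")
  } else {
    mu <- n1 * n2 / 2
    ties <- table(rk)
    sig <- sqrt(n1 * n2 / 12 *
                  ((n1 + n2 + 1) - sum(ties^3 - ties) /
                     ((n1 + n2) * (n1 + n2 - 1))))
    z <- (u - mu) / sig
    list(u = u, p = min(1, 2 * pnorm(-abs(z))),
         method = "normal approximation with tie correction")
  }
}

#' Compare abundance between high- and low-G+C genomes
#'
#' Per-genome mean RPKM is pooled into two groups split at `split`
#' (genomes exactly at the boundary join the high group) and compared
#' with a two-sided Mann-Whitney U test.
#'
#' @param abund RPKM matrix.
#' @param gc named per-genome G+C fractions.
#' @param split G+C boundary (default 0.45).
#' @return list: `p`, `u`, `method`, `direction` ("low>high" or
#'   "high>low"), `mean_low`, `mean_high`, `n_low`, `n_high`.
#' @export
group_compare <- function(abund, gc, split = 0.45) {
  gc <- gc[rownames(abund)]
  if (any(is.na(gc))) stop("missing G+C value for some genomes")
  means <- rowMeans(abund)
  hi <- means[gc >= split]
  lo <- means[gc < split]
  if (length(hi) == 0 || length(lo) == 0)
    stop("one G+C group is empty at split ", split)
  mw <- mann_whitney(lo, hi)
  list(p = mw$p, u = mw$u, method = mw$method,
       direction = if (mean(lo) >= mean(hi)) "low>high" else "high>low",
       mean_low = mean(lo), mean_high = mean(hi),
       n_low = length(lo), n_high = length(hi))
}
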