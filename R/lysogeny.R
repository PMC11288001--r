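# lysogeny: attP/attB attachment-site detection (maximal exact matches
# between phage and host), attL/attR junction detection from reads, and
# prophage detection inside bacterial contigs.

#' Find candidate attachment sites between a phage and its host
#'
#' Enumerates all maximal exact matches of length >= `min_len` between
#' the two genomes (both strands; k-mer anchored).  Sites are ranked by
#' overlap with a host tRNA (descending), then length (descending), then
#' phage coordinate.  attL/attR coordinates on the integrated map follow
#' Campbell integration arithmetic.  tRNA adjacency is a ranking
#' feature, never a filter.
#'
#' @param phage,host one-row genome tables.
#' @param host_trnas,phage_trnas optional feature tables; tRNA flags are
#'   FALSE when absent.
#' @param min_len minimum core length (>= 8; default 12).
#' @param near_bp distance within which a phage tRNA counts as "near".
#' @return data.frame of att sites (0-based half-open coordinates):
#'   `core`, `length`, `phage_start`, `phage_end`, `host_start`,
#'   `host_end`, `strand`, `overlaps_host_tRNA`, `near_phage_tRNA`,
#'   `attL_start`, `attL_end`, `attR_start`, `attR_end` (on the
#'   predicted lysogen).
#' @export
find_att <- function(phage, host, host_trnas = NULL, phage_trnas = NULL,
                     min_len = 12, near_bp = 1000) {
  if (min_len < 8) stop("min_len below the 8 bp noise floor")
  p <- phage$seq; h <- host$seq
  rows <- list()
  for (strand in c("+", "-")) {
    h2 <- if (strand == "+") h else revcomp(h)
    mems <- exact_matches(p, h2, min_len)
    if (nrow(mems) == 0) next
    if (strand == "-") {
      tmp <- mems$sstart
      mems$sstart <- nchar(h) - mems$send
      mems$send <- nchar(h) - tmp
    }
    mems$strand <- strand
    rows[[strand]] <- mems
  }
  if (length(rows) == 0)
    return(empty_att())
  m <- do.call(rbind, rows)
  m <- m[!duplicated(m[, c("qstart", "qend", "sstart", "send")]), ,
         drop = FALSE]
  core <- substr(rep(p, nrow(m)), m$qstart + 1, m$qend)
  over_trna <- rep(FALSE, nrow(m))
  if (!is.null(host_trnas)) {
    tr <- host_trnas[host_trnas$kind == "tRNA", , drop = FALSE]
    for (k in seq_len(nrow(tr)))
      over_trna <- over_trna | (m$sstart < tr$end[k] & m$send > tr$start[k])
  }
  near_ptrna <- rep(FALSE, nrow(m))
  if (!is.null(phage_trnas)) {
    tr <- phage_trnas[phage_trnas$kind == "tRNA", , drop = FALSE]
    for (k in seq_len(nrow(tr)))
      near_ptrna <- near_ptrna |
        (m$qstart >= tr$end[k] & m$qstart - tr$end[k] <= near_bp) |
        (m$qend <= tr$start[k] & tr$start[k] - m$qend <= near_bp)
  }
  len <- m$qend - m$qstart
  out <- data.frame(
    core = core, length = len,
    phage_start = m$qstart, phage_end = m$qend,
    host_start = m$sstart, host_end = m$send,
    strand = m$strand,
    overlaps_host_tRNA = over_trna, near_phage_tRNA = near_ptrna,
    attL_start = m$sstart, attL_end = m$send,
    attR_start = m$sstart + phage$length_bp,
    attR_end = m$send + phage$length_bp,
    stringsAsFactors = FALSE)
  out <- out[order(-out$overlaps_host_tRNA, -out$length, out$phage_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_att <- function() {
  data.frame(core = character(0), length = integer(0),
             phage_start = integer(0), phage_end = integer(0),
             host_start = integer(0), host_end = integer(0),
             strand = character(0), overlaps_host_tRNA = logical(0),
             near_phage_tRNA = logical(0), attL_start = integer(0),
             attL_end = integer(0), attR_start = integer(0),
             attR_end = integer(0), stringsAsFactors = FALSE)
}

# maximal exact matches >= min_len between q and s (forward orientations),
# 0-based half-open output
exact_matches <- function(q, s, min_len) {
  nq <- nchar(q); ns <- nchar(s)
  none <- data.frame(qstart = integer(0), qend = integer(0),
                     sstart = integer(0), send = integer(0))
  if (min(nq, ns) < min_len) return(none)
  k <- min_len
  qk <- substring(q, 1:(nq - k + 1), k:nq)
  sk <- substring(s, 1:(ns - k + 1), k:ns)
  qt <- data.table::data.table(kmer = qk, qpos = seq_along(qk))
  st <- data.table::data.table(kmer = sk, spos = seq_along(sk))
  hits <- merge(qt, st, by = "kmer", allow.cartesian = TRUE)
  if (nrow(hits) == 0) return(none)
  diags <- sort(unique(hits$qpos - hits$spos))
  rows <- list()
  for (d in diags) {
    qi <- max(1L, 1L + d); si <- qi - d
    len <- min(nq - qi, ns - si) + 1L
    if (len < k) next
    mv <- match_vector(q, s, qi, si, len)
    r <- rle(mv)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values == 1L & r$lengths >= k)
    for (w in ok)
      rows[[length(rows) + 1L]] <- data.frame(
        qstart = qi + starts[w] - 2L, qend = qi + ends[w] - 1L,
        sstart = si + starts[w] - 2L, send = si + ends[w] - 1L)
  }
  if (length(rows) == 0) return(none)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Detect phage-host junctions (attL/attR) from reads
#'
#' Reads are locally matched to the phage; reads with at least
#' `clip_min` unaligned terminal bases whose clipped part matches the
#' host at >= `id_min` identity are junction evidence.  Evidence is
#' clustered by phage breakpoint position (+/- `cluster_bp`), and
#' clusters with >= `min_reads` reads are reported with a consensus
#' breakpoint.
#'
#' @param reads character vector of reads (or a FASTQ path).
#' @param phage,host one-row genome tables.
#' @param clip_min minimum clip length (default 20; error if reads are
#'   shorter than `2 * clip_min`).
#' @param id_min identity gate for the clipped part on the host.
#' @param cluster_bp clustering tolerance (default 3).
#' @param min_reads cluster support threshold (default 2).
#' @return data.frame of clusters: `side` ("left" = host on the read's
#'   left flank), `phage_pos` (1-based consensus breakpoint on the
#'   phage), `n_reads`, `host_pos` (1-based consensus on the host).
#' @export
junction_detect <- function(reads, phage, host, clip_min = 20,
                            id_min = 0.95, cluster_bp = 3, min_reads = 2) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_fastq(reads)
  if (length(reads) > 0 && min(nchar(reads)) < 2 * clip_min)
    stop("reads shorter than 2 * clip_min")
  maps <- map_read_segments(reads, phage$seq, k = 15)
  ev <- list()
  if (!is.null(maps)) {
    maps <- maps[maps$identity >= id_min, , drop = FALSE]
    for (r in seq_len(nrow(maps))) {
      mp <- maps[r, ]
      rd <- reads[mp$read]
      rl <- nchar(rd)
      left_clip <- mp$qstart - 1L
      right_clip <- rl - mp$qend
      # "side" is in PHAGE orientation: left = host flank adjoins the
      # phage segment start, right = it adjoins the segment end
      if (left_clip >= clip_min) {
        cl <- substr(rd, 1, left_clip)
        hh <- clip_on_host(cl, host, id_min)
        if (!is.null(hh)) {
          side <- if (mp$strand == "+") "left" else "right"
          ev[[length(ev) + 1L]] <- data.frame(
            side = side,
            phage_pos = if (side == "left") mp$sstart else mp$send,
            host_pos = if (side == "left") hh["send"] else hh["sstart"])
        }
      }
      if (right_clip >= clip_min) {
        cl <- substr(rd, mp$qend + 1L, rl)
        hh <- clip_on_host(cl, host, id_min)
        if (!is.null(hh)) {
          side <- if (mp$strand == "+") "right" else "left"
          ev[[length(ev) + 1L]] <- data.frame(
            side = side,
            phage_pos = if (side == "left") mp$sstart else mp$send,
            host_pos = if (side == "left") hh["send"] else hh["sstart"])
        }
      }
    }
  }
  if (length(ev) == 0)
    return(data.frame(side = character(0), phage_pos = integer(0),
                      n_reads = integer(0), host_pos = integer(0),
                      stringsAsFactors = FALSE))
  e <- do.call(rbind, ev)
  out <- list()
  for (sd in unique(e$side)) {
    es <- e[e$side == sd, , drop = FALSE]
    es <- es[order(es$phage_pos), , drop = FALSE]
    grp <- cumsum(c(1L, diff(es$phage_pos) > cluster_bp))
    for (g in split(es, grp)) {
      if (nrow(g) < min_reads) next
      out[[length(out) + 1L]] <- data.frame(
        side = sd, phage_pos = round(median(g$phage_pos)),
        n_reads = nrow(g), host_pos = round(median(g$host_pos)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(side = character(0), phage_pos = integer(0),
                      n_reads = integer(0), host_pos = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$phage_pos), , drop = FALSE]
}

# best host position of a clipped fragment, or NULL if it fails the gate;
# returns the host coordinate adjacent to the junction
clip_on_host <- function(clip, host, id_min) {
  k <- min(15L, nchar(clip))
  hits <- tryCatch(nt_seed_extend(setNames(clip, "c"),
                                  setNames(host$seq, host$id),
                                  k = k, min_score = k),
                   error = function(e) NULL)
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  top <- hits[1, ]
  if (top$identity < id_min ||
      top$aligned_cols < 0.8 * nchar(clip)) return(NULL)
  c(sstart = top$sstart, send = top$send)
}

#' Detect prophages in bacterial contigs
#'
#' Seed-and-extend segments between each phage reference and contig are
#' chained; a call is made when the chained coverage of the phage
#' reference is >= `cov_min` and the length-weighted identity is
#' >= `id_min`.  Boundaries are the outermost chained segment ends, with
#' 5 kb of flanking host context recorded.
#'
#' @param phage_refs genome table of reference phages.
#' @param bacterial_contigs genome table (contigs >= 1 kb).
#' @param id_min,cov_min,e_max call gates (defaults 0.95, 0.5, 1e-3).
#' @param flank_bp host context span (default 5000).
#' @return data.frame: `contig_id`, `phage_ref`, 0-based half-open
#'   `start`/`end`, `mean_identity`, `ref_coverage`, `n_segments`,
#'   `flank_left_start`, `flank_right_end`.
#' @export
find_prophage <- function(phage_refs, bacterial_contigs, id_min = 0.95,
                          cov_min = 0.5, e_max = 1e-3, flank_bp = 5000) {
  calls <- list()
  for (ci in seq_len(nrow(bacterial_contigs))) {
    contig <- bacterial_contigs[ci, ]
    if (contig$length_bp < 1000) next
    for (ri in seq_len(nrow(phage_refs))) {
      ref <- phage_refs[ri, ]
      segs <- nt_seed_extend(setNames(ref$seq, ref$id),
                             setNames(contig$seq, contig$id), k = 15)
      segs <- segs[segs$evalue <= e_max, , drop = FALSE]
      if (nrow(segs) == 0) next
      cov <- sum(segs$aligned_cols) / ref$length_bp
      ident <- sum(segs$matches) / sum(segs$aligned_cols)
      if (cov < cov_min || ident < id_min) next
      s0 <- min(segs$sstart) - 1L
      e0 <- max(segs$send)
      calls[[length(calls) + 1L]] <- data.frame(
        contig_id = contig$id, phage_ref = ref$id, start = s0, end = e0,
        mean_identity = ident, ref_coverage = min(1, cov),
        n_segments = nrow(segs),
        flank_left_start = max(0L, s0 - flank_bp),
        flank_right_end = min(contig$length_bp, e0 + flank_bp),
        stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0)
    return(data.frame(contig_id = character(0), phage_ref = character(0),
                      start = integer(0), end = integer(0),
                      mean_identity = numeric(0), ref_coverage = numeric(0),
                      n_segments = integer(0), flank_left_start = integer(0),
                      flank_right_end = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, calls)
}
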