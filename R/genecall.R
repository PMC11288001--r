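# genecall: a minimal deterministic six-frame ORF scanner standing in for
# a trained gene finder, so the pipeline runs on bare nucleotide input.
# Real-genome workflows can import an external GFF instead.

codon_table <- function() {
  if (is.null(.align_env$codons)) {
    gc <- Biostrings::GENETIC_CODE   # bacterial table 11 shares these aa assignments
    .align_env$codons <- setNames(as.character(gc), names(gc))
  }
  .align_env$codons
}

START_CODONS <- c("ATG", "GTG", "TTG")

translate_codons <- function(codons) {
  tab <- codon_table()
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"   # codons containing N
  aa
}

#' Translate a called region back to protein
#'
#' Start codon is rendered as M (initiator methionine); the terminal stop
#' is dropped.
#'
#' @param seq genome sequence (forward strand).
#' @param start,end 0-based half-open region; `(end - start)` must be a
#'   multiple of 3 and include the stop codon.
#' @param strand "+" or "-".
#' @export
translate_region <- function(seq, start, end, strand = "+") {
  stopifnot((end - start) %% 3 == 0)
  sub <- substr(seq, start + 1, end)
  if (strand == "-") sub <- revcomp(sub)
  n <- nchar(sub)
  codons <- substring(sub, seq(1, n - 2, 3), seq(3, n, 3))
  aa <- translate_codons(codons)
  aa <- aa[-length(aa)]  # stop
  aa[1] <- "M"
  paste(aa, collapse = "")
}

#' Call open reading frames in six frames
#'
#' Scans both strands in all three frames; starts are ATG/GTG/TTG, stops
#' per the bacterial code.  Within one stop-bounded frame segment only
#' the maximal (earliest-start) ORF is reported; ORFs shorter than
#' `min_aa` codons of protein are dropped.  Overlapping calls on opposite
#' strands are all kept.  No partial ORFs are called at sequence edges.
#'
#' @param genome one-row genome table (or list with `id`, `seq`).
#' @param min_aa minimum protein length in residues (default 30).
#' @return data.frame sorted by start then strand: `genome_id`, `orf_id`
#'   (`<genome>_ORF<n>`, n 1-based in genome order), 0-based half-open
#'   `start`/`end` on forward-strand coordinates (stop codon included),
#'   `strand`, `gene_index`, `protein`.
#' @export
call_orfs <- function(genome, min_aa = 30) {
  gid <- genome$id; s <- genome$seq
  L <- nchar(s)
  if (L < 3 * (min_aa + 1)) stop("genome shorter than one minimal ORF")
  calls <- list()
  for (strand in c("+", "-")) {
    w <- if (strand == "+") s else revcomp(s)
    for (f in 0:2) {
      ncod <- (L - f) %/% 3
      if (ncod < min_aa + 2) next
      starts0 <- f + 3 * (seq_len(ncod) - 1)           # 0-based codon starts
      codons <- substring(w, starts0 + 1, starts0 + 3)
      aa <- translate_codons(codons)
      stop_idx <- which(aa == "*")
      if (length(stop_idx) == 0) next
      is_start <- codons %in% START_CODONS
      seg_begin <- c(1L, head(stop_idx, -1) + 1L)      # segments ending at stops
      for (si in seq_along(stop_idx)) {
        b <- seg_begin[si]; e <- stop_idx[si]
        if (e - b < min_aa) next                       # protein = e - start_codon
        cand <- which(is_start[b:(e - 1)])
        if (length(cand) == 0) next
        st_codon <- b + cand[1] - 1L
        prot_len <- e - st_codon
        if (prot_len < min_aa) next
        a0 <- starts0[st_codon]                        # on strand w
        b0 <- starts0[e] + 3L
        if (strand == "+") {
          fs <- a0; fe <- b0
        } else {
          fs <- L - b0; fe <- L - a0
        }
        prot <- paste(c("M", aa[(st_codon + 1):(e - 1)]), collapse = "")
        calls[[length(calls) + 1L]] <- list(start = fs, end = fe,
                                            strand = strand, protein = prot)
      }
    }
  }
  if (length(calls) == 0)
    return(data.frame(genome_id = character(0), orf_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), gene_index = integer(0),
                      protein = character(0), stringsAsFactors = FALSE))
  df <- data.frame(
    genome_id = gid,
    start = vapply(calls, `[[`, numeric(1), "start"),
    end = vapply(calls, `[[`, numeric(1), "end"),
    strand = vapply(calls, `[[`, character(1), "strand"),
    protein = vapply(calls, `[[`, character(1), "protein"),
    stringsAsFactors = FALSE)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  df$gene_index <- seq_len(nrow(df))
  df$orf_id <- paste0(gid, "_ORF", df$gene_index)
  rownames(df) <- NULL
  df[, c("genome_id", "orf_id", "start", "end", "strand", "gene_index",
         "protein")]
}

#' Call ORFs for every genome in a collection
#'
#' @param genomes genome table.
#' @inheritParams call_orfs
#' @return combined data.frame over all genomes.
#' @export
call_orfs_all <- function(genomes, min_aa = 30) {
  out <- lapply(seq_len(nrow(genomes)), function(i)
    call_orfs(genomes[i, ], min_aa = min_aa))
  do.call(rbind, out)
}

#' Suppress shadow ORFs
#'
#' Gene finders discard "shadow" calls: ORFs largely contained within a
#' longer call on another strand or frame.  For any pair of overlapping
#' calls on the same genome where the overlap covers at least `min_frac`
#' of the shorter call, the shorter call is dropped when the longer one
#' exceeds it by at least `len_margin`; near-equal-length overlaps are
#' resolved by a crude coding-potential score — amino-acid composition
#' typicality, the mean per-residue log-likelihood under the background
#' frequencies — dropping the clearly more atypical call (frame shadows
#' of G+C-biased coding sequence have strongly skewed composition).
#' Pairs that are ambiguous under both rules are kept.
#'
#' @param calls data.frame from [call_orfs_all()].
#' @param min_frac overlap fraction of the shorter call (default 0.5).
#' @param len_margin length ratio of longer to shorter above which
#'   length alone decides (default 1.2).
#' @param typ_margin composition log-likelihood difference (nats per
#'   residue) above which typicality decides (default 0.1).
#' @export
suppress_shadows <- function(calls, min_frac = 0.5, len_margin = 1.2,
                             typ_margin = 0.1) {
  keep <- rep(TRUE, nrow(calls))
  typ <- composition_typicality(calls$protein)
  for (gid in unique(calls$genome_id)) {
    ix <- which(calls$genome_id == gid)
    d <- calls[ix, ]
    ord <- order(-(d$end - d$start))
    for (a in seq_along(ord)) {
      ia <- ord[a]
      if (!keep[ix[ia]]) next
      for (b in seq_along(ord)) {
        if (b <= a) next
        ib <- ord[b]
        if (!keep[ix[ib]]) next
        ov <- min(d$end[ia], d$end[ib]) - max(d$start[ia], d$start[ib])
        len_a <- d$end[ia] - d$start[ia]
        len_b <- d$end[ib] - d$start[ib]
        if (ov < min_frac * len_b) next
        if (len_a >= len_margin * len_b) {
          keep[ix[ib]] <- FALSE
        } else {
          ta <- typ[ix[ia]]; tb <- typ[ix[ib]]
          if (ta - tb > typ_margin) keep[ix[ib]] <- FALSE
          else if (tb - ta > typ_margin) keep[ix[ia]] <- FALSE
        }
        if (!keep[ix[ia]]) break
      }
    }
  }
  calls[keep, , drop = FALSE]
}

# composition typicality = negative KL divergence (nats) of the
# protein's empirical amino-acid composition from the background;
# 0 is perfectly typical, frame shadows of G+C-biased coding sequence
# score strongly negative.  X and other non-standard letters ignored.
composition_typicality <- function(proteins) {
  aas <- names(AA_BACKGROUND)
  vapply(proteins, function(p) {
    cnt <- table(factor(chars(p), levels = aas))
    n <- sum(cnt)
    if (n == 0) return(-Inf)
    obs <- as.numeric(cnt) / n
    nz <- obs > 0
    -sum(obs[nz] * log(obs[nz] / AA_BACKGROUND[nz]))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Write gene calls as protein FASTA and GFF3
#' @param calls data.frame from [call_orfs_all()].
#' @param faa_path,gff_path output paths (NULL to skip one).
#' @export
write_gene_calls <- function(calls, faa_path = NULL, gff_path = NULL) {
  if (!is.null(faa_path))
    write_fasta(setNames(calls$protein, calls$orf_id), faa_path)
  if (!is.null(gff_path))
    write_gff(feature_table(calls$genome_id, calls$start, calls$end,
                            calls$strand, "CDS", calls$orf_id), gff_path)
  invisible(calls)
}
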