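# seqio: FASTA/GFF3/TSV/newick readers and writers plus basic genome
# statistics.  The package-wide coordinate convention lives here:
# internally every interval is 0-based half-open; every emitted text
# format (GFF3, BLAST-style tables) is 1-based inclusive.

#' Construct a genome record table
#'
#' Genomes are held as a plain data.frame with one row per record and
#' columns `id`, `seq`, `source`, `length_bp`.  Ids are whitespace-free
#' tokens, unique within a collection; sequences are upper-case strings
#' over A, C, G, T, N.
#'
#' @param id character vector of unique ids (no whitespace).
#' @param seq character vector of nucleotide sequences.
#' @param source provenance tag: one of `"isolate"`, `"uvig"`, `"host"`,
#'   `"synthetic"`.
#' @return data.frame with columns id, seq, source, length_bp.
#' @export
genome_set <- function(id, seq, source = "synthetic") {
  stopifnot(length(id) == length(seq))
  if (anyDuplicated(id))
    stop("duplicate genome id: ", id[duplicated(id)][1])
  if (any(grepl("[[:space:]]", id)))
    stop("genome ids must not contain whitespace")
  seq <- toupper(seq)
  seq <- gsub("U", "T", seq, fixed = TRUE)
  bad <- regexpr("[^ACGTN]", seq)
  if (any(bad > 0)) {
    k <- which(bad > 0)[1]
    stop(sprintf("invalid character '%s' at position %d in record '%s'",
                 substr(seq[k], bad[k], bad[k]), bad[k], id[k]))
  }
  source <- match.arg(source, c("isolate", "uvig", "host", "synthetic"),
                      several.ok = TRUE)
  data.frame(id = as.character(id), seq = seq,
             source = rep_len(source, length(id)),
             length_bp = nchar(seq), stringsAsFactors = FALSE)
}

#' Read a nucleotide FASTA file into a genome record table
#'
#' Sequences are upper-cased and U is mapped to T; characters outside
#' A, C, G, T, N, U are rejected with the offending position.  Duplicate
#' headers and empty files are errors.
#'
#' @param path FASTA file (optionally gzipped).
#' @param source provenance tag recorded on every record.
#' @return data.frame as from [genome_set()].
#' @export
read_fasta <- function(path, source = "uvig") {
  if (!file.exists(path)) stop("no such file: ", path)
  xs <- Biostrings::readBStringSet(path)
  if (length(xs) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(xs))
  genome_set(ids, as.character(xs), source = source)
}

#' Write a genome record table (or named character vector) as FASTA
#'
#' Multi-record FASTA wrapped at 70 columns.
#'
#' @param x genome table from [genome_set()] or a named character vector.
#' @param path output file.
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) x <- setNames(x$seq, x$id)
  stopifnot(!is.null(names(x)))
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a protein FASTA file
#'
#' @param path FASTA file.
#' @param gaps if TRUE, keep `-` gap characters (aligned FASTA / MSA input);
#'   all rows must then have equal length.
#' @return named character vector of upper-case amino-acid strings.
#' @export
read_protein_fasta <- function(path, gaps = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  xs <- Biostrings::readBStringSet(path)
  if (length(xs) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(xs))
  if (anyDuplicated(ids)) stop("duplicate id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(xs))
  ok <- if (gaps) "[^ACDEFGHIKLMNPQRSTVWYX*-]" else "[^ACDEFGHIKLMNPQRSTVWYX*]"
  bad <- regexpr(ok, seqs)
  if (any(bad > 0)) {
    k <- which(bad > 0)[1]
    stop(sprintf("invalid residue at position %d in '%s'", bad[k], ids[k]))
  }
  if (gaps && length(unique(nchar(seqs))) > 1)
    stop("aligned FASTA rows have unequal lengths")
  setNames(seqs, ids)
}

#' G+C content of a sequence
#'
#' Fraction (G+C)/(A+C+G+T); N is excluded from numerator and denominator.
#' Reports use [format_percent()] with two decimals.
#'
#' @param x a genome table row, single sequence string, or vector of strings.
#' @return numeric fraction(s) in `[0, 1]`.
#' @export
gc_content <- function(x) {
  if (is.data.frame(x)) x <- x$seq
  vapply(x, function(s) {
    n <- nchar(s)
    gc <- n - nchar(gsub("[GC]", "", s))
    at <- n - nchar(gsub("[AT]", "", s))
    if (gc + at == 0) stop("gc_content undefined: no non-N bases")
    gc / (gc + at)
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname gc_content
#' @param frac fraction in `[0, 1]`.
#' @export
format_percent <- function(frac) sprintf("%.2f%%", 100 * frac)

#' Genome length in kb at report precision
#' @param bp length in base pairs.
#' @export
kb <- function(bp) round(bp / 1000, 1)

#' Construct a feature table
#'
#' Features use 0-based half-open coordinates internally.
#'
#' @param genome_id,start,end,strand,kind,label vectors of equal length;
#'   `start`/`end` 0-based half-open, `strand` in `+`/`-`, `kind` one of
#'   `CDS`, `tRNA`, `other`.
#' @return data.frame with those columns.
#' @export
feature_table <- function(genome_id, start, end, strand = "+",
                          kind = "CDS", label = "") {
  n <- length(genome_id)
  stopifnot(all(start >= 0), all(end > start))
  stopifnot(all(strand %in% c("+", "-")))
  stopifnot(all(kind %in% c("CDS", "tRNA", "other")))
  data.frame(genome_id = as.character(genome_id),
             start = as.integer(start), end = as.integer(end),
             strand = rep_len(strand, n), kind = rep_len(kind, n),
             label = rep_len(as.character(label), n),
             stringsAsFactors = FALSE)
}

# Shared 0-based half-open <-> 1-based inclusive conversion.  Every text
# format writer/reader goes through these two.
to_gff_coords <- function(start0, end0) {
  stopifnot(all(end0 > start0))
  list(start = as.integer(start0 + 1L), end = as.integer(end0))
}

from_gff_coords <- function(start1, end1) {
  stopifnot(all(start1 >= 1), all(end1 >= start1))
  list(start = as.integer(start1 - 1L), end = as.integer(end1))
}

#' Write features as GFF3
#'
#' Internal 0-based half-open coordinates are converted to the GFF3
#' 1-based inclusive dialect.
#'
#' @param features data.frame from [feature_table()], sorted by
#'   (genome_id, start).
#' @param path output file.
#' @param genome_lengths optional named vector; features exceeding their
#'   genome length are an error.
#' @export
write_gff <- function(features, path, genome_lengths = NULL) {
  f <- features[order(features$genome_id, features$start), , drop = FALSE]
  if (!is.null(genome_lengths)) {
    len <- genome_lengths[f$genome_id]
    if (any(is.na(len)) || any(f$end > len))
      stop("feature exceeds genome length")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(f) > 0) {
    cc <- to_gff_coords(f$start, f$end)
    attr_col <- ifelse(f$label == "", ".", paste0("Name=", f$label))
    lines <- paste(f$genome_id, "phamily", f$kind, cc$start, cc$end,
                   ".", f$strand, ".", attr_col, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a GFF3 file into a feature table (0-based half-open)
#'
#' @param path GFF3 file.
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0)
    return(feature_table(character(0), integer(0), integer(0))[0, ])
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9)) stop("malformed GFF3 line")
  m <- do.call(rbind, parts)
  cc <- from_gff_coords(as.integer(m[, 4]), as.integer(m[, 5]))
  label <- ifelse(grepl("Name=", m[, 9]),
                  sub("^.*Name=([^;]*).*$", "\\1", m[, 9]), "")
  kind <- ifelse(m[, 3] %in% c("CDS", "tRNA"), m[, 3], "other")
  feature_table(m[, 1], cc$start, cc$end, m[, 7], kind, label)
}

#' Write/read a plain TSV with header row
#' @param x data.frame.
#' @param path file path.
#' @export
write_tsv_file <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_file
#' @export
read_tsv_file <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a phylogenetic tree in newick format
#' @param tree an [ape::phylo] object (support values in `node.label`).
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
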