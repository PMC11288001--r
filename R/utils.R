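# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Single stated PRNG for the whole package: Mersenne-Twister with
# Inversion normals, as initialised here.  All stochastic entry points
# take an integer seed and route through this.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Derive a stream-specific child seed (kept below 2^31).
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 9973) %% 2147483647
}

# data.table queries are used inside this package
.datatable.aware <- TRUE

# reverse complement of plain character DNA strings (vectorised)
revcomp <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Adjusted Rand Index between two labelings (Hubert & Arabie).
ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == e) return(1)
  (sij - e) / (mx - e)
}

# deterministic md5 of a file (content hash for manifests)
file_hash <- function(path) unname(tools::md5sum(path))

roman <- function(i) as.character(utils::as.roman(i))
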