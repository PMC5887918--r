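#' Sequence string helpers
#'
#' Small vectorised utilities for nucleotide strings represented as plain
#' character vectors. All pipeline functions store sequences as character
#' columns in tibbles; `Biostrings` objects are created only at alignment
#' and file-IO boundaries.
#'
#' @param x character vector of nucleotide sequences (A/C/G/T).
#' @return `revcomp()` the reverse complement; `hamming()` an integer
#'   vector of positionwise mismatches (sequences must be equal length).
#' @examples
#' revcomp("ACGT")
#' hamming("AAAA", "AATA")
#' @name seq-utils
NULL

#' @rdname seq-utils
#' @export
revcomp <- function(x) {
  stringi_rev(chartr("ACGT", "TGCA", stringr::str_to_upper(x)))
}

# stringr has no reverse; do it with utf8 splitting (sequences are ASCII)
stringi_rev <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' @rdname seq-utils
#' @param y second character vector, recycled against `x`.
#' @export
hamming <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) return(integer(0))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  if (any(nchar(x) != nchar(y))) {
    abort("hamming() requires equal-length sequences", class = "dietlink_param_error")
  }
  mapply(function(a, b) {
    sum(charToRaw(a) != charToRaw(b))
  }, x, y, USE.NAMES = FALSE)
}

# random sequence of length n over ACGT
random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# substitute exactly k random positions (to a different base)
mutate_positions <- function(seq, k) {
  if (k == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(ch), k)
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    ch[p] <- sample(setdiff(bases, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

# per-base iid substitution errors at rate `rate` on each sequence
apply_substitution_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n_err <- rbinom(1L, nchar(s), rate)
    mutate_positions(s, n_err)
  }, character(1), USE.NAMES = FALSE)
}

#' Read and write FASTA as tibbles
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that keep reads in the tidy
#' `(read_id, sequence)` form used throughout the pipeline.
#'
#' @param path file path.
#' @param reads tibble with columns `read_id`, `sequence`.
#' @return `read_fasta()` returns a tibble with `read_id` and `sequence`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(read_id = names(ss), sequence = unname(as.character(ss)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(set_names(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname read_fasta
#' @param quality constant Phred quality character used for every base.
#' @export
write_fastq <- function(reads, path, quality = "I") {
  ss <- Biostrings::DNAStringSet(set_names(reads$sequence, reads$read_id))
  q <- Biostrings::BStringSet(strrep(quality, nchar(reads$sequence)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = q)
  invisible(path)
}

# zero-truncated Poisson with *truncated-distribution* mean `mean`
rztpois <- function(n, mean) {
  stopifnot(mean > 1)
  lambda <- ztpois_rate(mean)
  p0 <- exp(-lambda)
  stats::qpois(runif(n, p0, 1), lambda)
}

# solve lambda / (1 - exp(-lambda)) = m
ztpois_rate <- function(m) {
  stats::uniroot(function(l) l / (1 - exp(-l)) - m,
                 lower = 1e-8, upper = m + 1, tol = 1e-10)$root
}

# weighted sampling of k distinct items, inclusion by successive draws
# with probability proportional to w (PPSWOR), via the exponential-race
# construction: the k smallest Exp(1)/w_i keys are exactly a successive
# weighted draw without replacement.
sample_distinct <- function(w, k) {
  stopifnot(k <= sum(w > 0))
  keys <- rexp(length(w)) / w
  order(keys)[seq_len(k)]
}
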