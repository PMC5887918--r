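#' Pairwise sequence identity from global alignment
#'
#' Identity between two nucleotide sequences under a Needleman-Wunsch
#' global alignment with match +1, mismatch -1 and a linear gap penalty
#' of -2 per gap column. Identity is the number of matching columns
#' divided by the total alignment length *including* gap columns, so
#' terminal gaps count against identity. This is the primitive behind
#' MOTU clustering thresholds and the >98% barcode-assignment rule.
#'
#' @param a,b nonempty nucleotide strings.
#' @param match,mismatch,gap alignment scores (gap is the per-column
#'   linear gap penalty, given as a negative number).
#' @return a fraction in \[0, 1\]; symmetric in its arguments.
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT")
#' pairwise_identity("AAAA", "AATA")
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(a) || !nzchar(b)) {
    abort("pairwise_identity() requires nonempty sequences",
          class = "dietlink_param_error")
  }
  identity_to_refs(a, b, match = match, mismatch = mismatch, gap = gap)[1]
}

# identity of one query against a character vector of references,
# vectorised through a single pairwiseAlignment call
identity_to_refs <- function(query, refs, match = 1, mismatch = -1, gap = -2) {
  if (length(refs) == 0L) return(numeric(0))
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(refs), Biostrings::DNAString(query),
    type = "global", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = abs(gap))
  n_match <- Biostrings::nmatch(aln)
  aln_len <- nchar(as.character(Biostrings::pattern(aln)))
  as.numeric(n_match / aln_len)
}

# lazily-filled symmetric identity cache over a fixed sequence set;
# returns a closure get(i, j_vec) -> identities. Used so the threshold
# grid search aligns each haplotype pair at most once.
identity_cache <- function(seqs, ...) {
  n <- length(seqs)
  mat <- matrix(NA_real_, n, n)
  diag(mat) <- 1
  function(i, js) {
    missing <- js[is.na(mat[i, js])]
    if (length(missing)) {
      ids <- identity_to_refs(seqs[i], seqs[missing], ...)
      mat[i, missing] <<- ids
      mat[missing, i] <<- ids
    }
    mat[i, js]
  }
}
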