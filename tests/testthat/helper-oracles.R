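# Independent oracle implementations used to cross-check package code.
# These deliberately re-derive results by the most transparent route
# available (enumeration, closed forms, naive loops).

# all permutations of a vector (n <= 6 in tests)
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

pianka_raw <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# exact RA3 null distribution of Pianka overlap for two small vectors:
# every pair of row permutations, equally likely
enumerate_overlap_null <- function(p_j, p_k) {
  pj <- perms(p_j)
  pk <- perms(p_k)
  unlist(lapply(pj, function(a) vapply(pk, function(b) pianka_raw(a, b),
                                       numeric(1))))
}

# naive greedy centroid clustering, written independently of the
# package: ordering and join rule recomputed from scratch with direct
# pairwise_identity calls
brute_force_clusters <- function(haplotypes, threshold) {
  pooled <- aggregate(copy_count ~ sequence, data = haplotypes, FUN = sum)
  pooled <- pooled[order(-pooled$copy_count, pooled$sequence), ]
  centroids <- character(0)
  assignment <- integer(nrow(pooled))
  for (i in seq_len(nrow(pooled))) {
    joined <- 0L
    for (ci in seq_along(centroids)) {
      if (pairwise_identity(pooled$sequence[i], centroids[ci]) >= threshold) {
        joined <- ci
        break
      }
    }
    if (joined == 0L) {
      centroids <- c(centroids, pooled$sequence[i])
      joined <- length(centroids)
    }
    assignment[i] <- joined
  }
  list(sequence = pooled$sequence, assignment = assignment,
       centroids = centroids)
}

# accumulation curve as the average over explicit random orderings
permutation_accumulation <- function(m, n_perm, seed = 1) {
  set.seed(seed)
  M <- nrow(m)
  acc <- numeric(M)
  for (p in seq_len(n_perm)) {
    ord <- sample.int(M)
    seen <- rep(FALSE, ncol(m))
    for (n in seq_len(M)) {
      seen <- seen | (m[ord[n], ] > 0)
      acc[n] <- acc[n] + sum(seen)
    }
  }
  acc / n_perm
}

# small deterministic barcode fixture builders -------------------------

fixture_db <- function(n_prey = 6, within = 0.01, between = 0.10, seed = 42) {
  generate_reference_db(n_prey, haplotypes_per_taxon = 2, seq_length = 287,
                        between_taxon_divergence = between,
                        within_taxon_divergence = within, seed = seed)
}

# haplotype table straight from db records (each record seen in one
# individual with a given copy count)
db_haplotypes <- function(db, copies = 5) {
  tibble::tibble(individual_id = sprintf("ind%02d", seq_len(nrow(db))),
                 sequence = db$sequence, copy_count = copies)
}
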