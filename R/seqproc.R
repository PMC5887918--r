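#' Demultiplex MID-tagged amplicon reads
#'
#' Splits pooled reads by their forward/reverse multiplex identifier
#' (MID) tags and strips MIDs and primers, leaving the bare template. A
#' read is assigned iff both observed MIDs resolve (within
#' `max_mismatch` Hamming mismatches, uniquely) to registered tags whose
#' pair is in the registry; everything else lands in the unassigned bin
#' (`individual_id` = NA).
#'
#' @param reads tibble with `read_id`, `sequence`.
#' @param mid_map registry tibble `(forward_mid, reverse_mid,
#'   individual_id)`; pairs must be unique. Rows with NA individual_id
#'   are unassigned combinations and reads carrying them stay binned.
#' @param max_mismatch allowed Hamming mismatches per MID (default 0:
#'   with 10-bp tags at pairwise distance >= 3, exact matching is safe).
#' @param fwd_primer,rev_primer primer sequences to strip after the MIDs.
#' @return tibble `(read_id, individual_id, sequence)` where `sequence`
#'   is the trimmed template and `individual_id` is NA for unassigned
#'   reads.
#' @export
demultiplex <- function(reads, mid_map, max_mismatch = 0,
                        fwd_primer = DEFAULT_FWD_PRIMER,
                        rev_primer = DEFAULT_REV_PRIMER) {
  pairs <- paste(mid_map$forward_mid, mid_map$reverse_mid)
  if (anyDuplicated(pairs)) {
    abort("duplicate (forward, reverse) MID pair in registry",
          class = "dietlink_config_error")
  }
  mid_len <- unique(nchar(c(mid_map$forward_mid, mid_map$reverse_mid)))
  if (length(mid_len) != 1L) {
    abort("all MIDs must have equal length", class = "dietlink_config_error")
  }
  n <- nchar(reads$sequence)
  fmid_obs <- substr(reads$sequence, 1L, mid_len)
  rmid_obs <- revcomp(substring(reads$sequence, n - mid_len + 1L, n))

  fwd_tags <- unique(mid_map$forward_mid)
  rev_tags <- unique(mid_map$reverse_mid)
  f_res <- resolve_mid(fmid_obs, fwd_tags, max_mismatch)
  r_res <- resolve_mid(rmid_obs, rev_tags, max_mismatch)

  key <- paste(f_res, r_res)
  idx <- match(key, pairs)
  individual_id <- mid_map$individual_id[idx]

  lead <- mid_len + nchar(fwd_primer)
  trail <- mid_len + nchar(rev_primer)
  template <- substring(reads$sequence, lead + 1L, pmax(n - trail, lead))
  tibble(read_id = reads$read_id,
         individual_id = individual_id,
         sequence = ifelse(is.na(individual_id), reads$sequence, template))
}

# map observed tags to registered tags within max_mismatch (unique best
# hit required); returns NA where unresolved
resolve_mid <- function(obs, tags, max_mismatch) {
  if (max_mismatch == 0) {
    return(tags[match(obs, tags)])
  }
  uobs <- unique(obs)
  res <- vapply(uobs, function(o) {
    if (nchar(o) != nchar(tags[1])) return(NA_character_)
    d <- hamming(tags, o)
    hit <- which(d <= max_mismatch & d == min(d))
    if (length(hit) == 1L) tags[hit] else NA_character_
  }, character(1))
  res[match(obs, uobs)]
}

#' Filter reads by template length
#'
#' Retains reads whose trimmed length lies in `[min_len, max_len]`
#' inclusive (the marker's expected 260-300 bp window).
#'
#' @param reads tibble with a `sequence` column.
#' @param min_len,max_len inclusive bounds.
#' @export
length_filter <- function(reads, min_len = 260, max_len = 300) {
  if (min_len > max_len) {
    abort("min_len must be <= max_len", class = "dietlink_param_error")
  }
  filter(reads, nchar(.data$sequence) >= min_len,
         nchar(.data$sequence) <= max_len)
}

#' Collapse reads into per-individual haplotypes
#'
#' Exact-identity collapse of each individual's reads into unique
#' haplotypes; haplotypes seen fewer than `min_copies` times in that
#' individual are discarded (rare-haplotype noise filter).
#'
#' @param reads tibble with `individual_id`, `sequence` (assigned reads
#'   only; NA individuals are dropped).
#' @param min_copies minimum per-individual copy count (default 2).
#' @return tibble `(individual_id, sequence, copy_count)`.
#' @export
collapse_haplotypes <- function(reads, min_copies = 2) {
  reads |>
    filter(!is.na(.data$individual_id)) |>
    count(.data$individual_id, .data$sequence, name = "copy_count") |>
    filter(.data$copy_count >= min_copies) |>
    arrange(.data$individual_id, desc(.data$copy_count), .data$sequence)
}

#' Greedy centroid MOTU clustering at a similarity threshold
#'
#' Pools haplotypes across individuals and clusters them into molecular
#' operational taxonomic units: haplotypes are processed in decreasing
#' total copy count (ties broken by lexicographic sequence order); each
#' haplotype joins the first existing centroid with pairwise identity >=
#' `threshold`, otherwise it founds a new cluster whose centroid
#' (representative) it becomes. Deterministic and invariant to input
#' row order.
#'
#' @param haplotypes tibble `(individual_id, sequence, copy_count)` from
#'   [collapse_haplotypes()].
#' @param threshold similarity threshold in (0, 1).
#' @param idfun optional identity lookup `function(i, js)` over the
#'   pooled unique sequences in processing order (internal cache reuse).
#' @return list of class `motu_table`: `threshold`, `members` tibble
#'   `(motu_id, sequence, individual_id, copy_count)` and
#'   `representatives` tibble `(motu_id, sequence, total_copies,
#'   n_haplotypes)`.
#' @export
cluster_motus <- function(haplotypes, threshold, idfun = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  pooled <- pooled_haplotypes(haplotypes)
  if (nrow(pooled) == 0L) {
    abort("no haplotypes to cluster", class = "dietlink_param_error")
  }
  idfun <- idfun %||% identity_cache(pooled$sequence)
  centroid_idx <- integer(0)           # indices (into pooled) of centroids
  assignment <- integer(nrow(pooled))  # motu index per pooled haplotype
  for (i in seq_len(nrow(pooled))) {
    hit <- 0L
    if (length(centroid_idx)) {
      ids <- idfun(i, centroid_idx)
      ok <- which(ids >= threshold)
      if (length(ok)) hit <- ok[1]     # first centroid in founding order
    }
    if (hit == 0L) {
      centroid_idx <- c(centroid_idx, i)
      assignment[i] <- length(centroid_idx)
    } else {
      assignment[i] <- hit
    }
  }
  pooled$motu_id <- sprintf("motu%03d", assignment)
  members <- haplotypes |>
    left_join(pooled[, c("sequence", "motu_id")], by = "sequence") |>
    select("motu_id", "sequence", "individual_id", "copy_count") |>
    arrange(.data$motu_id, desc(.data$copy_count))
  # representative = the centroid (founder) of each cluster
  representatives <- tibble(
    motu_id = sprintf("motu%03d", seq_along(centroid_idx)),
    sequence = pooled$sequence[centroid_idx]
  ) |>
    left_join(pooled |>
                group_by(.data$motu_id) |>
                summarise(total_copies = sum(.data$total_copies),
                          n_haplotypes = dplyr::n(), .groups = "drop"),
              by = "motu_id")
  structure(list(threshold = threshold, members = members,
                 representatives = representatives),
            class = "motu_table")
}

# unique sequences pooled across individuals in the defined processing
# order: decreasing total copy count, ties lexicographic
pooled_haplotypes <- function(haplotypes) {
  haplotypes |>
    group_by(.data$sequence) |>
    summarise(total_copies = sum(.data$copy_count), .groups = "drop") |>
    arrange(desc(.data$total_copies), .data$sequence)
}

#' Assign MOTU representatives to reference taxa
#'
#' Best-hit assignment of each representative against every barcode
#' record. If the best identity is not strictly greater than
#' `min_identity` the MOTU is `no_match`; if the single best hit is a
#' contaminant record the MOTU is `contaminant`. Otherwise all hits
#' within `consensus_window` (0.5% identity) of the best are collected
#' and the MOTU is assigned at species rank when they agree on the
#' species, else at the lowest rank (genus, family, order) shared by all
#' hits — a desk-scale stand-in for multi-hit consensus taxonomy.
#'
#' @param representatives character vector of sequences, or a tibble
#'   with `motu_id` and `sequence` columns.
#' @param db a `barcode_db`.
#' @param min_identity assignment floor (assign only when best identity
#'   is `> min_identity`).
#' @param consensus_window identity window below the best hit whose
#'   members vote on the consensus rank.
#' @return tibble `(motu_id, sequence, taxon, rank, identity)` where
#'   `rank` is one of species/genus/family/order/contaminant/no_match
#'   and `taxon` is the label at that rank (NA for no_match).
#' @export
assign_taxonomy <- function(representatives, db, min_identity = 0.98,
                            consensus_window = 0.005) {
  if (nrow(db) == 0L) {
    abort("empty barcode db", class = "dietlink_param_error")
  }
  if (is.character(representatives)) {
    representatives <- tibble(motu_id = sprintf("motu%03d",
                                                seq_along(representatives)),
                              sequence = representatives)
  }
  purrr::pmap(representatives[, c("motu_id", "sequence")],
              function(motu_id, sequence) {
    ids <- identity_to_refs(sequence, db$sequence)
    best <- max(ids)
    if (best <= min_identity) {
      return(tibble(motu_id, sequence, taxon = NA_character_,
                    rank = "no_match", identity = best))
    }
    best_rec <- db[which.max(ids), ]
    if (best_rec$is_contaminant) {
      return(tibble(motu_id, sequence, taxon = best_rec$species_label,
                    rank = "contaminant", identity = best))
    }
    hits <- db[ids >= best - consensus_window & !db$is_contaminant, ]
    res <- if (length(unique(hits$species_label)) == 1L) {
      c(hits$species_label[1], "species")
    } else if (length(unique(hits$genus)) == 1L) {
      c(hits$genus[1], "genus")
    } else if (length(unique(hits$family)) == 1L) {
      c(hits$family[1], "family")
    } else {
      c(hits$order[1], "order")
    }
    tibble(motu_id, sequence, taxon = res[1], rank = res[2], identity = best)
  }) |> list_rbind()
}

# split-best-hit chimera heuristic: each half of the representative is
# aligned (half global, reference local) against the db; the MOTU is
# flagged chimeric when the two halves' best hits name different taxa
# and both halves match at >= min_identity
is_chimeric <- function(sequence, db, min_identity = 0.98) {
  n <- nchar(sequence)
  if (n < 4L) return(FALSE)
  halves <- c(substr(sequence, 1L, n %/% 2L),
              substr(sequence, n %/% 2L + 1L, n))
  hits <- lapply(halves, function(h) {
    ids <- half_identity(h, db$sequence)
    list(taxon = db$taxon_id[which.max(ids)], identity = max(ids))
  })
  hits[[1]]$identity >= min_identity && hits[[2]]$identity >= min_identity &&
    hits[[1]]$taxon != hits[[2]]$taxon
}

# identity of a fragment aligned globally within locally-aligned refs
half_identity <- function(fragment, refs) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(refs), Biostrings::DNAString(fragment),
    type = "local-global", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = 2)
  n_match <- Biostrings::nmatch(aln)
  aln_len <- nchar(as.character(Biostrings::pattern(aln)))
  as.numeric(n_match / aln_len)
}

#' Select the optimal MOTU clustering threshold over a grid
#'
#' Clusters the pooled haplotypes at every threshold of the grid
#' (default 0.97 down to 0.87 in steps of 0.01), assigns taxonomy at
#' each, and picks the threshold with the lowest number of species
#' (excluding chimeric MOTUs) allocated multiple MOTUs, subject to
#' retaining the majority (>= 50% of the grid maximum) of species-level
#' assignments; ties break toward the higher threshold.
#'
#' @param haplotypes tibble from [collapse_haplotypes()].
#' @param db a `barcode_db`.
#' @param grid decreasing vector of thresholds.
#' @param min_identity assignment floor passed to [assign_taxonomy()].
#' @param majority retained fraction of the maximum species-assignment
#'   count defining "the majority".
#' @return list of class `threshold_selection`: `threshold` (t_opt),
#'   `diagnostics` tibble `(threshold, n_motus,
#'   species_with_multiple_motus, n_species_assignments)`, `motus` and
#'   `assignments` at t_opt.
#' @export
select_threshold <- function(haplotypes, db,
                             grid = seq(0.97, 0.87, by = -0.01),
                             min_identity = 0.98, majority = 0.5) {
  stopifnot(length(grid) > 0)
  if (nrow(haplotypes) == 0L) {
    abort("empty haplotype set", class = "dietlink_param_error")
  }
  pooled <- pooled_haplotypes(haplotypes)
  idfun <- identity_cache(pooled$sequence)
  assign_cache <- new.env(parent = emptyenv())
  chim_cache <- new.env(parent = emptyenv())

  per_t <- lapply(grid, function(t) {
    motus <- cluster_motus(haplotypes, t, idfun = idfun)
    reps <- motus$representatives
    asg <- purrr::map(reps$sequence, function(s) {
      if (is.null(assign_cache[[s]])) {
        assign_cache[[s]] <- assign_taxonomy(s, db,
                                             min_identity = min_identity)[1, ]
      }
      assign_cache[[s]]
    }) |> list_rbind()
    asg$motu_id <- reps$motu_id
    asg$chimeric <- vapply(asg$sequence, function(s) {
      if (is.null(chim_cache[[s]])) {
        chim_cache[[s]] <- is_chimeric(s, db, min_identity)
      }
      chim_cache[[s]]
    }, logical(1), USE.NAMES = FALSE)
    sp <- asg[asg$rank == "species" & !asg$chimeric, ]
    diag <- tibble(
      threshold = t,
      n_motus = nrow(reps),
      species_with_multiple_motus =
        sum(table(sp$taxon) > 1L),
      n_species_assignments = nrow(sp)
    )
    list(motus = motus, assignments = asg, diag = diag)
  })
  diagnostics <- list_rbind(purrr::map(per_t, "diag"))
  keep <- diagnostics$n_species_assignments >=
    majority * max(diagnostics$n_species_assignments)
  cand <- diagnostics[keep, ]
  best <- cand$threshold[order(cand$species_with_multiple_motus,
                               -cand$threshold)][1]
  i_best <- which(grid == best)
  structure(list(threshold = best,
                 diagnostics = diagnostics,
                 motus = per_t[[i_best]]$motus,
                 assignments = per_t[[i_best]]$assignments),
            class = "threshold_selection")
}

#' Per-individual taxon detections from clustered, assigned MOTUs
#'
#' Joins MOTU membership with taxonomy to produce the tidy detection
#' table consumed by [build_diet_matrix()].
#'
#' @param motus a `motu_table` from [cluster_motus()].
#' @param assignments tibble from [assign_taxonomy()] for the same MOTUs.
#' @return tibble `(individual_id, motu_id, taxon, rank, identity,
#'   n_haplotypes, n_reads)`.
#' @export
motu_detections <- function(motus, assignments) {
  motus$members |>
    group_by(.data$individual_id, .data$motu_id) |>
    summarise(n_haplotypes = dplyr::n(), n_reads = sum(.data$copy_count),
              .groups = "drop") |>
    left_join(assignments[, c("motu_id", "taxon", "rank", "identity")],
              by = "motu_id") |>
    arrange(.data$individual_id, .data$motu_id)
}

#' Run the full read-to-detection stage
#'
#' Convenience wrapper: demultiplex, length-filter, collapse haplotypes,
#' select the MOTU threshold over a grid, and emit per-individual
#' detections.
#'
#' @inheritParams demultiplex
#' @inheritParams select_threshold
#' @param min_len,max_len length-filter bounds.
#' @param min_copies rare-haplotype floor.
#' @return list of class `seqproc_result`: `detections`, `threshold`,
#'   `diagnostics`, `motus`, `assignments`, `haplotypes`, and counts of
#'   assigned/unassigned reads.
#' @export
process_reads <- function(reads, mid_map, db,
                          grid = seq(0.97, 0.87, by = -0.01),
                          min_copies = 2, min_len = 260, max_len = 300,
                          max_mismatch = 0,
                          fwd_primer = DEFAULT_FWD_PRIMER,
                          rev_primer = DEFAULT_REV_PRIMER,
                          min_identity = 0.98) {
  demux <- demultiplex(reads, mid_map, max_mismatch, fwd_primer, rev_primer)
  assigned <- filter(demux, !is.na(.data$individual_id))
  kept <- length_filter(assigned, min_len, max_len)
  haps <- collapse_haplotypes(kept, min_copies)
  sel <- select_threshold(haps, db, grid = grid, min_identity = min_identity)
  det <- motu_detections(sel$motus, sel$assignments)
  structure(list(detections = det,
                 threshold = sel$threshold,
                 diagnostics = sel$diagnostics,
                 motus = sel$motus,
                 assignments = sel$assignments,
                 haplotypes = haps,
                 n_assigned = nrow(assigned),
                 n_unassigned = nrow(demux) - nrow(assigned)),
            class = "seqproc_result")
}
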