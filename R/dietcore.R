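#' Build a presence/absence diet matrix from detections
#'
#' Converts per-individual MOTU detections into the binary
#' individual x prey-taxon incidence matrix on which all diet analyses
#' are based (read counts cannot reliably quantify prey biomass, so
#' everything downstream is presence/absence). Contaminant and no-match
#' detections are dropped; detected taxa are merged to the analysis
#' taxonomy via `rank_map` (typically the taxonomic level of the kick
#' samples); detections of the individual's own species are dropped
#' because cannibalism is molecularly unresolvable; duplicates collapse
#' to a single 1.
#'
#' @param detections tibble with `individual_id`, `taxon`, `rank` (from
#'   [motu_detections()], or any table with those columns).
#' @param rank_map named character vector or tibble
#'   `(taxon, analysis_taxon)` mapping every detected taxon label to its
#'   analysis-level taxon. Unmapped taxa are an error.
#' @param metadata tibble `(individual_id, predator_species, site_id,
#'   season)`; every individual in `detections` must appear. Individuals
#'   with no retained detections keep an all-zero row.
#' @return a tibble of class `diet_matrix`: the four metadata columns
#'   followed by one 0/1 column per analysis taxon.
#' @export
build_diet_matrix <- function(detections, rank_map, metadata) {
  stopifnot(all(c("individual_id", "taxon") %in% names(detections)),
            all(DIET_ID_COLS %in% names(metadata)))
  if (is.data.frame(rank_map)) {
    rank_map <- set_names(rank_map$analysis_taxon, rank_map$taxon)
  }
  det <- detections
  if ("rank" %in% names(det)) {
    det <- filter(det, !.data$rank %in% c("contaminant", "no_match"))
  }
  det <- filter(det, !is.na(.data$taxon))
  unmapped <- setdiff(unique(det$taxon), names(rank_map))
  if (length(unmapped)) {
    abort(paste("taxa missing from rank_map:", paste(unmapped, collapse = ", ")),
          class = "dietlink_param_error")
  }
  det$analysis_taxon <- unname(rank_map[det$taxon])

  missing_meta <- setdiff(unique(det$individual_id), metadata$individual_id)
  if (length(missing_meta)) {
    abort(paste("individuals missing from metadata:",
                paste(missing_meta, collapse = ", ")),
          class = "dietlink_param_error")
  }
  det <- det |>
    left_join(metadata[, c("individual_id", "predator_species")],
              by = "individual_id") |>
    filter(.data$analysis_taxon != .data$predator_species) |>
    distinct(.data$individual_id, .data$analysis_taxon) |>
    mutate(present = 1L)

  wide <- metadata[, DIET_ID_COLS] |>
    left_join(tidyr::pivot_wider(det, names_from = "analysis_taxon",
                                 values_from = "present", values_fill = 0L),
              by = "individual_id") |>
    mutate(across(!dplyr::all_of(DIET_ID_COLS), ~ tidyr::replace_na(.x, 0L)))
  taxa <- sort(setdiff(names(wide), DIET_ID_COLS))
  out <- wide[, c(DIET_ID_COLS, taxa)]
  class(out) <- c("diet_matrix", class(out))
  out
}

#' Prey-taxon columns of a diet matrix
#' @param diet a `diet_matrix`.
#' @export
diet_taxa <- function(diet) setdiff(names(diet), DIET_ID_COLS)

# numeric incidence block of a diet matrix
diet_incidence <- function(diet) {
  as.matrix(diet[, diet_taxa(diet), drop = FALSE])
}

#' Mean number of prey taxa detected per individual
#'
#' @param diet a `diet_matrix`.
#' @param by optional character vector of metadata columns to stratify
#'   by; with `NULL` a single number is returned.
#' @return a number, or a tibble with the grouping columns and
#'   `mean_prey`.
#' @export
mean_prey_per_individual <- function(diet, by = NULL) {
  if (nrow(diet) == 0L) {
    abort("empty stratum", class = "dietlink_param_error")
  }
  rs <- rowSums(diet_incidence(diet))
  if (is.null(by)) return(mean(rs))
  diet |>
    mutate(.n_prey = rs) |>
    group_by(across(dplyr::all_of(by))) |>
    summarise(n_individuals = dplyr::n(), mean_prey = mean(.data$.n_prey),
              .groups = "drop")
}

#' Utilization proportions from a diet matrix
#'
#' The utilization vector of a stratum is the proportion of positive
#' detections falling on each taxon: (individuals positive for taxon) /
#' (total positives across taxa). It is the input to the niche breadth
#' and overlap statistics.
#'
#' @param diet a `diet_matrix`.
#' @param by optional metadata columns to stratify by (e.g.
#'   `"predator_species"`).
#' @return tibble with grouping columns, `taxon`, `n_positive`, `p`;
#'   within each stratum `sum(p) == 1` whenever any positives exist.
#' @export
utilization <- function(diet, by = NULL) {
  taxa <- diet_taxa(diet)
  long <- diet |>
    tidyr::pivot_longer(dplyr::all_of(taxa), names_to = "taxon",
                        values_to = "present") |>
    group_by(across(dplyr::all_of(c(by, "taxon")))) |>
    summarise(n_positive = sum(.data$present), .groups = "drop_last") |>
    mutate(p = if (sum(.data$n_positive) > 0)
      .data$n_positive / sum(.data$n_positive) else 0) |>
    ungroup()
  long
}

#' @rdname utilization
#' @return `utilization_vector()` a named numeric vector of proportions
#'   over the matrix's taxa (pooled over all rows).
#' @export
utilization_vector <- function(diet) {
  u <- utilization(diet)
  set_names(u$p, u$taxon)
}

#' Levins' standardized niche breadth
#'
#' `B = 1 / sum(p^2)` rescaled to `B_A = (B - 1) / (n_available - 1)`,
#' which controls for the number of potential prey so breadths are
#' comparable across locations. 0 = complete specialization on one
#' taxon, 1 = uniform use of all available taxa.
#'
#' @param p utilization proportions (must sum to 1; zero entries
#'   allowed).
#' @param n_available number of potential prey taxa in the stratum
#'   (e.g. taxa with nonzero kick-sample abundance); must be >= 2 and >=
#'   the number of taxa used.
#' @return `B_A` in \[0, 1\].
#' @examples
#' levins_breadth(c(0.5, 0.25, 0.25), n_available = 5)
#' @export
levins_breadth <- function(p, n_available) {
  if (n_available < 2) {
    abort("n_available must be >= 2", class = "dietlink_param_error")
  }
  if (all(p == 0)) {
    abort("degenerate utilization vector (all zero)",
          class = "dietlink_param_error")
  }
  if (abs(sum(p) - 1) > 1e-8) {
    abort("utilization proportions must sum to 1",
          class = "dietlink_param_error")
  }
  B <- 1 / sum(p^2)
  (B - 1) / (n_available - 1)
}

#' Pianka's niche overlap
#'
#' Symmetric resource-overlap index between two consumers:
#' `O_jk = sum(p_j * p_k) / sqrt(sum(p_j^2) * sum(p_k^2))`, 0 for
#' disjoint resource use, 1 for identical use.
#'
#' @param p_j,p_k utilization vectors over a common taxon support. If
#'   both are named they are aligned on the union of names (absent taxa
#'   count as 0); unnamed vectors must have equal length.
#' @return overlap in \[0, 1\].
#' @examples
#' pianka_overlap(c(0.5, 0.5, 0), c(0, 0.5, 0.5))
#' @export
pianka_overlap <- function(p_j, p_k) {
  al <- align_support(p_j, p_k)
  p_j <- al[[1]]; p_k <- al[[2]]
  if (all(p_j == 0) || all(p_k == 0)) {
    abort("zero utilization vector", class = "dietlink_param_error")
  }
  sum(p_j * p_k) / sqrt(sum(p_j^2) * sum(p_k^2))
}

align_support <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    taxa <- union(names(x), names(y))
    xx <- set_names(rep(0, length(taxa)), taxa); xx[names(x)] <- x
    yy <- set_names(rep(0, length(taxa)), taxa); yy[names(y)] <- y
    list(xx, yy)
  } else {
    if (length(x) != length(y)) {
      abort("vectors must share a common taxon support",
            class = "dietlink_param_error")
    }
    list(x, y)
  }
}

#' Overall prey-selection strength
#'
#' Scalar summary of how far observed per-taxon consumption frequencies
#' sit from their null-model expectations:
#' `S = sum(|o_t - e_t|) / (sum(o_t) + sum(e_t))`. S = 0 iff observed
#' and expected are identical; S = 1 iff their supports are disjoint
#' (no overlap between observed and expected consumption). Note the
#' denominator: normalising by observed totals alone would allow values
#' up to 2 and break the stated \[0, 1\] characterization, so the sum of
#' both totals is used.
#'
#' @param observed,expected nonnegative per-taxon frequencies on the
#'   same support (named vectors are aligned by name).
#' @return S in \[0, 1\].
#' @examples
#' selection_strength(c(6, 2, 2), c(4, 4, 2))
#' @export
selection_strength <- function(observed, expected) {
  al <- align_support(observed, expected)
  o <- al[[1]]; e <- al[[2]]
  if (sum(o) + sum(e) <= 0) {
    abort("observed and expected both sum to zero",
          class = "dietlink_param_error")
  }
  sum(abs(o - e)) / (sum(o) + sum(e))
}
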