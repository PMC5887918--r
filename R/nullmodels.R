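#' Randomize a utilization matrix
#'
#' Null-model randomizations of a predators x taxa utilization matrix in
#' the EcoSim style. `RA3` (default, the framework's recommended
#' algorithm) permutes each row's values across taxon slots, preserving
#' the multiset of utilization values (and hence each predator's niche
#' breadth); `RA2` keeps the zero structure and redraws nonzero entries
#' uniformly on (0, 1).
#'
#' @param mat numeric matrix, rows = predators, columns = taxa.
#' @param algorithm `"RA3"` or `"RA2"`.
#' @param seed integer seed.
#' @return matrix of the same dimension.
#' @export
randomize_utilization <- function(mat, algorithm = c("RA3", "RA2"),
                                  seed = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(is.matrix(mat), is.numeric(mat))
  maybe_with_seed(seed, {
    out <- mat
    for (r in seq_len(nrow(mat))) {
      if (algorithm == "RA3") {
        out[r, ] <- mat[r, sample.int(ncol(mat))]
      } else {
        nz <- mat[r, ] > 0
        out[r, nz] <- runif(sum(nz))
      }
    }
    out
  })
}

#' Monte-Carlo test of niche overlap
#'
#' Compares the observed Pianka overlap of two predators against the
#' distribution of overlaps across randomized utilization matrices.
#' `proportion_exceeded` is the fraction of simulated overlaps strictly
#' below the observed value — the probability that the observed overlap
#' is greater than expected at random; values above 0.95 indicate
#' significantly high overlap. Both tail fractions are reported since
#' the direction of interest may differ.
#'
#' @param p_j,p_k utilization vectors (named vectors are aligned on the
#'   union of their taxa).
#' @param n_iterations Monte-Carlo iterations (default 10,000; fewer
#'   than 100 triggers a warning).
#' @param algorithm randomization algorithm, see
#'   [randomize_utilization()].
#' @param seed integer seed.
#' @return object of class `overlap_test` with the observed overlap,
#'   null summary, tail proportions and the simulated null overlaps.
#' @export
overlap_null_test <- function(p_j, p_k, n_iterations = 10000,
                              algorithm = c("RA3", "RA2"), seed = NULL) {
  algorithm <- match.arg(algorithm)
  if (n_iterations < 100) {
    warn("fewer than 100 iterations gives unstable tail estimates")
  }
  al <- align_support(p_j, p_k)
  mat <- rbind(al[[1]], al[[2]])
  observed <- pianka_overlap(mat[1, ], mat[2, ])
  maybe_with_seed(seed, {
    null_o <- vapply(seq_len(n_iterations), function(i) {
      r <- randomize_utilization(mat, algorithm)
      sum(r[1, ] * r[2, ]) / sqrt(sum(r[1, ]^2) * sum(r[2, ]^2))
    }, numeric(1))
    structure(list(
      observed = observed,
      null_mean = mean(null_o),
      null_quantiles = quantile(null_o, c(0.025, 0.5, 0.975), names = TRUE),
      proportion_exceeded = mean(null_o < observed),
      proportion_above = mean(null_o > observed),
      n_iterations = n_iterations,
      algorithm = algorithm,
      seed = seed,
      null_overlaps = null_o
    ), class = "overlap_test")
  })
}

#' Null consumption counts under proportional-abundance feeding
#'
#' Core sampler of the prey-choice null model: each individual draws its
#' observed number of distinct prey taxa by successive weighted sampling
#' without replacement with inclusion probability proportional to
#' relative abundance; the per-iteration null statistic is the number of
#' individuals positive for each taxon. Implemented via the
#' exponential-race construction (the k smallest `Exp(1)/w` keys are a
#' successive weighted draw), which vectorises over individuals and
#' iterations.
#'
#' @param abundance positive-able nonnegative weight vector over taxa
#'   (relative abundances; need not sum to 1).
#' @param gut_sizes integer vector: distinct taxa observed per
#'   individual; each must be <= the number of taxa with positive
#'   abundance.
#' @param n_iterations number of null iterations.
#' @param seed integer seed.
#' @return integer matrix `n_iterations x length(abundance)` of null
#'   counts (columns named after `abundance` when it is named).
#' @export
null_consumption_counts <- function(abundance, gut_sizes, n_iterations,
                                    seed = NULL) {
  n_taxa <- length(abundance)
  if (sum(abundance) <= 0) {
    abort("abundance must have positive total", class = "dietlink_param_error")
  }
  n_pos <- sum(abundance > 0)
  if (any(gut_sizes > n_pos)) {
    abort("an individual's item count exceeds the number of available taxa",
          class = "dietlink_param_error")
  }
  maybe_with_seed(seed, {
    # chunk iterations to bound the exponential-key matrix at ~2e7 cells
    chunk <- max(1L, floor(2e7 / max(1L, length(gut_sizes) * n_taxa)))
    done <- 0L
    parts <- list()
    while (done < n_iterations) {
      it <- min(chunk, n_iterations - done)
      parts[[length(parts) + 1L]] <-
        null_counts_chunk(abundance, gut_sizes, it)
      done <- done + it
    }
    counts <- do.call(rbind, parts)
    colnames(counts) <- names(abundance)
    counts
  })
}

null_counts_chunk <- function(w, k, n_iter) {
  n_taxa <- length(w)
  n_ind <- length(k)
  counts <- matrix(0L, n_iter, n_taxa)
  kmax <- if (n_ind) max(k) else 0L
  if (kmax == 0L) return(counts)
  m <- n_ind * n_iter
  E <- matrix(rexp(m * n_taxa), nrow = m) /
    matrix(w, nrow = m, ncol = n_taxa, byrow = TRUE)
  k_row <- rep.int(k, n_iter)
  iter_of_row <- rep(seq_len(n_iter), each = n_ind)
  for (s in seq_len(kmax)) {
    j <- max.col(-E, ties.method = "first")
    active <- k_row >= s
    inc <- tabulate((j[active] - 1L) * n_iter + iter_of_row[active],
                    nbins = n_iter * n_taxa)
    counts <- counts + matrix(inc, n_iter, n_taxa)
    E[cbind(seq_len(m), j)] <- Inf
  }
  counts
}

#' Prey-choice null model with 95% confidence limits
#'
#' Tests for prey selection by comparing, per taxon, the observed number
#' of predator individuals testing positive against the distribution of
#' that count under the null model in which prey are consumed in
#' proportion to their relative (kick-sample) abundance. Each individual
#' keeps its observed gut size (number of distinct prey taxa). The
#' expected frequency is the mean over iterations and the confidence
#' limits are the 2.5/97.5 empirical percentiles (linear interpolation
#' between order statistics); a taxon is `preferred` when its observed
#' count exceeds the upper limit, `avoided` below the lower limit, and
#' `neutral` otherwise (ties at a limit are neutral). Seasons are the
#' natural pooling unit: pass a per-site abundance table to stratify the
#' null by site.
#'
#' @param diet a `diet_matrix` (typically one predator species; its own
#'   taxon is structurally absent). Gut sizes and observed counts are
#'   its row and column sums.
#' @param abundance either a named numeric vector of taxon abundances
#'   (single stratum) or a long tibble with columns `site_id`, `taxon`
#'   (or `taxon_id`) and `count` — counts are summed over any `season`
#'   column and the null is drawn per site. All diet-matrix taxa must
#'   appear in the abundance support.
#' @param n_iterations Monte-Carlo iterations (default 10,000).
#' @param conf confidence level for the limits (default 0.95).
#' @param seed integer seed.
#' @return object of class `selection_result`: `$table` is a tibble
#'   `(taxon, observed, expected, lower, upper, class)`;
#'   `$selection_strength` the scalar S over all taxa; plus run
#'   metadata.
#' @export
prey_choice_null <- function(diet, abundance, n_iterations = 10000,
                             conf = 0.95, seed = NULL) {
  stopifnot(inherits(diet, "diet_matrix") || is.data.frame(diet))
  ab <- normalize_abundance(abundance)
  taxa <- colnames(ab)
  extra <- setdiff(diet_taxa(diet), taxa)
  if (length(extra)) {
    abort(paste("diet taxa missing from abundance support:",
                paste(extra, collapse = ", ")),
          class = "dietlink_param_error")
  }
  inc <- diet_incidence(diet)
  observed <- set_names(rep(0L, length(taxa)), taxa)
  cs <- colSums(inc)
  observed[names(cs)] <- as.integer(cs)
  gut_sizes <- as.integer(rowSums(inc))

  strat <- if (nrow(ab) == 1L) rep(rownames(ab), nrow(diet)) else {
    if (!all(diet$site_id %in% rownames(ab))) {
      abort("diet matrix has sites absent from the abundance table",
            class = "dietlink_param_error")
    }
    diet$site_id
  }
  if (nrow(diet) == 0L) {
    abort("diet matrix has no individuals", class = "dietlink_param_error")
  }
  maybe_with_seed(seed, {
    counts <- matrix(0L, n_iterations, length(taxa),
                     dimnames = list(NULL, taxa))
    for (s in unique(strat)) {
      rows <- strat == s
      counts <- counts +
        null_consumption_counts(ab[s, ], gut_sizes[rows], n_iterations)
    }
    a <- (1 - conf) / 2
    expected <- colMeans(counts)
    lower <- apply(counts, 2, quantile, probs = a, names = FALSE)
    upper <- apply(counts, 2, quantile, probs = 1 - a, names = FALSE)
    cls <- dplyr::case_when(observed > upper ~ "preferred",
                            observed < lower ~ "avoided",
                            TRUE ~ "neutral")
    structure(list(
      table = tibble(taxon = taxa, observed = unname(observed),
                     expected = unname(expected), lower = unname(lower),
                     upper = unname(upper), class = cls),
      selection_strength = selection_strength(unname(observed),
                                              unname(expected)),
      n_iterations = n_iterations, conf = conf, seed = seed,
      n_individuals = nrow(diet)
    ), class = "selection_result")
  })
}

# accept a named vector or a long site x taxon tibble; returns a
# strata x taxa matrix (single row "all" for the vector form), pooling
# seasons by summation
normalize_abundance <- function(abundance) {
  if (is.numeric(abundance) && !is.null(names(abundance))) {
    return(matrix(abundance, nrow = 1,
                  dimnames = list("all", names(abundance))))
  }
  if (is.data.frame(abundance)) {
    ab <- as_tibble(abundance)
    if (!"taxon" %in% names(ab) && "taxon_id" %in% names(ab)) {
      ab <- rename(ab, taxon = "taxon_id")
    }
    stopifnot(all(c("site_id", "taxon", "count") %in% names(ab)))
    wide <- ab |>
      group_by(.data$site_id, .data$taxon) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "taxon", values_from = "count",
                         values_fill = 0)
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$site_id
    return(m)
  }
  abort("abundance must be a named vector or a site/taxon/count table",
        class = "dietlink_param_error")
}

#' Compare two predators' prey-selection classifications
#'
#' Cross-tabulates the per-taxon preference classes of two
#' [prey_choice_null()] results over the same taxon support and lists
#' the taxa jointly preferred and jointly avoided by both predators.
#'
#' @param result_j,result_k `selection_result` objects.
#' @return object of class `selection_comparison`: `$table` with
#'   per-taxon classes, `$jointly_preferred`, `$jointly_avoided`.
#' @export
compare_selection <- function(result_j, result_k) {
  tj <- result_j$table; tk <- result_k$table
  if (!identical(sort(tj$taxon), sort(tk$taxon))) {
    abort("selection results have mismatched taxon support",
          class = "dietlink_param_error")
  }
  tk <- tk[match(tj$taxon, tk$taxon), ]
  tab <- tibble(taxon = tj$taxon, class_j = tj$class, class_k = tk$class,
                joint = ifelse(tj$class == tk$class & tj$class != "neutral",
                               tj$class, "none"))
  structure(list(
    table = tab,
    jointly_preferred = tab$taxon[tab$joint == "preferred"],
    jointly_avoided = tab$taxon[tab$joint == "avoided"]
  ), class = "selection_comparison")
}
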