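#' Bray-Curtis dissimilarity with optional fourth-root transform
#'
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` on (optionally
#' fourth-root transformed) counts; the transform down-weights the most
#' abundant taxa. Computation is delegated to [vegan::vegdist()].
#'
#' @param counts sample x taxon table: a numeric matrix, or a data frame
#'   whose non-numeric columns are treated as sample labels.
#' @param transform `"none"` or `"fourth_root"`.
#' @return a `dist` object with a `transform` attribute.
#' @export
bray_curtis <- function(counts, transform = c("none", "fourth_root")) {
  transform <- match.arg(transform)
  m <- counts_matrix(counts)
  if (any(m < 0)) {
    abort("counts must be nonnegative", class = "dietlink_param_error")
  }
  if (any(rowSums(m) == 0)) {
    abort("all-zero sample row", class = "dietlink_param_error")
  }
  if (transform == "fourth_root") m <- m^0.25
  d <- vegan::vegdist(m, method = "bray")
  attr(d, "transform") <- transform
  d
}

counts_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  df <- as.data.frame(counts)
  num <- vapply(df, is.numeric, logical(1))
  m <- as.matrix(df[, num, drop = FALSE])
  labs <- df[, !num, drop = FALSE]
  rownames(m) <- if (ncol(labs)) do.call(paste, c(labs, sep = "_")) else
    rownames(df)
  m
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS in `k` dimensions via [vegan::monoMDS()] run
#' from `n_restarts` seeded random starts; the lowest-stress solution is
#' returned with centred scores.
#'
#' @param d a `dist` (e.g. from [bray_curtis()]).
#' @param k number of dimensions (default 2).
#' @param n_restarts random starts.
#' @param max_iter,tol optimizer controls passed to monoMDS.
#' @param seed integer seed.
#' @return object of class `nmds_ordination`: `$scores` (centred
#'   n x k matrix), `$stress`, `$n_restarts`, `$converged`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, max_iter = 500, tol = 1e-7,
                 seed = NULL) {
  n <- attr(d, "Size")
  if (is.null(n) || n < k + 2) {
    abort("need at least k + 2 samples", class = "dietlink_param_error")
  }
  maybe_with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- vegan::monoMDS(d, k = k, model = "global",
                            maxit = max_iter, sfgrmin = tol)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    scores <- scale(best$points, center = TRUE, scale = FALSE)
    colnames(scores) <- paste0("NMDS", seq_len(k))
    structure(list(scores = scores[, , drop = FALSE],
                   stress = best$stress,
                   n_restarts = n_restarts,
                   converged = best$icause %in% c(3, 4) || best$stress < 1e-4,
                   labels = labels(d)),
              class = "nmds_ordination")
  })
}

#' Permutational multivariate analysis of variance (one-way)
#'
#' Partitions the total sum of squared dissimilarities into between- and
#' within-group components and tests the pseudo-F statistic by permuting
#' group labels. `p = (1 + #{permuted F >= observed}) / (1 + n_perm)`.
#'
#' @param d a `dist`.
#' @param groups factor-like group labels, one per sample; at least two
#'   groups with >= 2 members each.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return object of class `permanova_test` with `statistic` (pseudo-F),
#'   `p_value`, `df`, `R2` and the permutation distribution.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  groups <- as.factor(groups)
  n <- attr(d, "Size")
  stopifnot(length(groups) == n)
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("need >= 2 groups with >= 2 members each",
          class = "dietlink_param_error")
  }
  D2 <- as.matrix(d)^2
  ss_total <- sum(D2) / (2 * n)
  g <- length(sizes)
  f_stat <- function(lab) {
    ssw <- 0
    for (lv in levels(lab)) {
      idx <- which(lab == lv)
      ssw <- ssw + sum(D2[idx, idx]) / (2 * length(idx))
    }
    ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))
  }
  observed <- f_stat(groups)
  maybe_with_seed(seed, {
    perm_f <- vapply(seq_len(n_perm), function(i) {
      f_stat(groups[sample.int(n)])
    }, numeric(1))
    structure(list(
      statistic = observed,
      p_value = (1 + sum(perm_f >= observed)) / (1 + n_perm),
      df = c(between = g - 1, within = n - g),
      R2 = {
        ssw <- 0
        for (lv in levels(groups)) {
          idx <- which(groups == lv)
          ssw <- ssw + sum(D2[idx, idx]) / (2 * length(idx))
        }
        (ss_total - ssw) / ss_total
      },
      n_perm = n_perm,
      perm_stats = perm_f
    ), class = "permanova_test")
  })
}

#' Fit a gradient vector to ordination scores
#'
#' Envfit-style vector fitting: `r` is the multiple correlation of the
#' covariate with its best-fitting direction in ordination score space
#' (the square root of the R^2 of regressing the centred covariate on
#' the scores); significance is assessed by permuting the covariate
#' across samples.
#'
#' @param scores an `nmds_ordination` or a numeric score matrix.
#' @param covariate per-sample numeric covariate (e.g. an agricultural
#'   intensity score).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return object of class `vector_fit` with `r`, `direction` (unit
#'   vector in score space), `p_value`, `n_perm`.
#' @export
vector_fit <- function(scores, covariate, n_perm = 999, seed = NULL) {
  S <- if (inherits(scores, "nmds_ordination")) scores$scores else
    as.matrix(scores)
  stopifnot(length(covariate) == nrow(S))
  if (sd(covariate) == 0) {
    abort("constant covariate", class = "dietlink_param_error")
  }
  S <- scale(S, center = TRUE, scale = FALSE)
  r_of <- function(v) {
    fit <- stats::lm.fit(S, v - mean(v))
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((v - mean(v))^2)
    sqrt(max(0, 1 - ss_res / ss_tot))
  }
  observed <- r_of(covariate)
  beta <- stats::lm.fit(S, covariate - mean(covariate))$coefficients
  direction <- beta / sqrt(sum(beta^2))
  maybe_with_seed(seed, {
    perm_r <- vapply(seq_len(n_perm), function(i) {
      r_of(covariate[sample.int(length(covariate))])
    }, numeric(1))
    structure(list(r = observed, direction = direction,
                   p_value = (1 + sum(perm_r >= observed)) / (1 + n_perm),
                   n_perm = n_perm, perm_stats = perm_r),
              class = "vector_fit")
  })
}

#' Species accumulation curve and incidence-based total richness
#'
#' Expected prey richness as a function of the number of predator
#' individuals examined. In `exact` mode the hypergeometric (sample-based
#' rarefaction) formula is used:
#' `E[S_n] = sum_t (1 - choose(M - M_t, n) / choose(M, n))` with `M`
#' individuals and `M_t` individuals containing taxon t; `permutation`
#' mode averages accumulation over random individual orderings. Total
#' richness is estimated by bias-corrected Chao2,
#' `S_obs + ((M-1)/M) * q1 (q1 - 1) / (2 (q2 + 1))`, from the counts of
#' taxa in exactly one (`q1`) and two (`q2`) individuals. The curve is
#' also summarised by the number of individuals needed to reach given
#' fractions of total richness (default 50% and 90%).
#'
#' @param incidence binary individuals x taxa matrix, or a
#'   `diet_matrix`.
#' @param mode `"exact"` or `"permutation"`.
#' @param n_perm orderings averaged in permutation mode.
#' @param fractions coverage fractions to locate on the curve.
#' @param fraction_of denominator for coverage: observed richness
#'   (default) or the Chao2 estimate.
#' @param seed integer seed (permutation mode).
#' @return object of class `accumulation_curve`: `$curve` tibble
#'   `(n, expected_richness)`, `$S_obs`, `$chao2`, `$q1`, `$q2`,
#'   `$n_for_fraction` tibble `(fraction, n, n_interpolated)`.
#' @export
accumulation_curve <- function(incidence, mode = c("exact", "permutation"),
                               n_perm = 1000, fractions = c(0.5, 0.9),
                               fraction_of = c("observed", "chao2"),
                               seed = NULL) {
  mode <- match.arg(mode)
  fraction_of <- match.arg(fraction_of)
  m <- if (inherits(incidence, "diet_matrix")) diet_incidence(incidence) else
    as.matrix(incidence)
  m <- (m > 0) * 1L
  M <- nrow(m)
  if (M < 1L) abort("empty incidence matrix", class = "dietlink_param_error")
  Mt <- colSums(m)
  present <- Mt > 0
  S_obs <- sum(present)
  q1 <- sum(Mt == 1)
  q2 <- sum(Mt == 2)
  chao2 <- S_obs + ((M - 1) / M) * q1 * (q1 - 1) / (2 * (q2 + 1))

  ns <- seq_len(M)
  expected <- if (mode == "exact") {
    vapply(ns, function(n) {
      sum(1 - exp(lchoose(M - Mt[present], n) - lchoose(M, n)))
    }, numeric(1))
  } else {
    maybe_with_seed(seed, {
      acc <- numeric(M)
      for (p in seq_len(n_perm)) {
        ord <- sample.int(M)
        seen <- apply(m[ord, , drop = FALSE], 2, cummax)
        acc <- acc + rowSums(seen > 0)
      }
      acc / n_perm
    })
  }
  denom <- if (fraction_of == "observed") S_obs else chao2
  nff <- purrr::map(fractions, function(f) {
    target <- f * denom
    hit <- which(expected >= target - 1e-9)
    n_exact <- if (length(hit)) ns[hit[1]] else NA_integer_
    n_interp <- if (!length(hit)) NA_real_ else if (hit[1] == 1L) 1 else {
      i <- hit[1]
      ns[i - 1] + (target - expected[i - 1]) /
        (expected[i] - expected[i - 1])
    }
    tibble(fraction = f, n = n_exact, n_interpolated = n_interp)
  }) |> list_rbind()

  structure(list(curve = tibble(n = ns, expected_richness = expected),
                 S_obs = S_obs, chao2 = chao2, q1 = q1, q2 = q2,
                 mode = mode, fraction_of = fraction_of,
                 n_for_fraction = nff),
            class = "accumulation_curve")
}

#' Rarefied richness of one sample
#'
#' Expected number of taxa in a random subsample of `depth` individuals
#' drawn without replacement from one sample's counts (hypergeometric
#' expectation): `sum_i (1 - choose(N - N_i, depth) / choose(N, depth))`.
#'
#' @param counts nonnegative taxon counts for one sample.
#' @param depth subsample size; must be <= `sum(counts)`.
#' @return expected richness (a number).
#' @examples
#' rarefied_richness(c(5, 5), 2)
#' @export
rarefied_richness <- function(counts, depth) {
  N <- sum(counts)
  if (depth > N) {
    abort("depth exceeds total count", class = "dietlink_param_error")
  }
  ci <- counts[counts > 0]
  sum(1 - exp(lchoose(N - ci, depth) - lchoose(N, depth)))
}
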