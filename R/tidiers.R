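#' Tidy and glance methods for dietlink result objects
#'
#' broom-style accessors: `tidy()` returns the per-unit table of a
#' result (per taxon, per threshold, per sample point), `glance()` a
#' one-row summary of the fit/test.
#'
#' @param x a dietlink result object.
#' @param ... unused.
#' @name dietlink-tidiers
NULL

#' @rdname dietlink-tidiers
#' @export
tidy.selection_result <- function(x, ...) x$table

#' @rdname dietlink-tidiers
#' @export
glance.selection_result <- function(x, ...) {
  tibble(selection_strength = x$selection_strength,
         n_taxa = nrow(x$table),
         n_preferred = sum(x$table$class == "preferred"),
         n_avoided = sum(x$table$class == "avoided"),
         n_individuals = x$n_individuals,
         n_iterations = x$n_iterations,
         conf = x$conf)
}

#' @rdname dietlink-tidiers
#' @export
tidy.overlap_test <- function(x, ...) {
  tibble(statistic = "pianka_overlap",
         observed = x$observed,
         null_mean = x$null_mean,
         null_lower = unname(x$null_quantiles[1]),
         null_upper = unname(x$null_quantiles[3]),
         proportion_exceeded = x$proportion_exceeded)
}

#' @rdname dietlink-tidiers
#' @export
glance.overlap_test <- function(x, ...) {
  tibble(observed = x$observed,
         null_mean = x$null_mean,
         proportion_exceeded = x$proportion_exceeded,
         proportion_above = x$proportion_above,
         significant_high = x$proportion_exceeded > 0.95,
         n_iterations = x$n_iterations,
         algorithm = x$algorithm)
}

#' @rdname dietlink-tidiers
#' @export
tidy.permanova_test <- function(x, ...) {
  tibble(term = c("groups", "residual"),
         df = unname(x$df),
         statistic = c(x$statistic, NA),
         R2 = c(x$R2, 1 - x$R2),
         p_value = c(x$p_value, NA))
}

#' @rdname dietlink-tidiers
#' @export
glance.permanova_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, R2 = x$R2,
         n_perm = x$n_perm)
}

#' @rdname dietlink-tidiers
#' @export
tidy.nmds_ordination <- function(x, ...) {
  as_tibble(x$scores) |>
    mutate(sample = x$labels %||% as.character(seq_len(nrow(x$scores))),
           .before = 1)
}

#' @rdname dietlink-tidiers
#' @export
glance.nmds_ordination <- function(x, ...) {
  tibble(stress = x$stress, k = ncol(x$scores), n_restarts = x$n_restarts,
         converged = x$converged)
}

#' @rdname dietlink-tidiers
#' @export
tidy.accumulation_curve <- function(x, ...) x$curve

#' @rdname dietlink-tidiers
#' @export
glance.accumulation_curve <- function(x, ...) {
  out <- tibble(S_obs = x$S_obs, chao2 = x$chao2, q1 = x$q1, q2 = x$q2,
                mode = x$mode)
  for (i in seq_len(nrow(x$n_for_fraction))) {
    out[[sprintf("n_%d", round(100 * x$n_for_fraction$fraction[i]))]] <-
      x$n_for_fraction$n[i]
  }
  out
}

#' @rdname dietlink-tidiers
#' @export
tidy.vector_fit <- function(x, ...) {
  tibble(axis = names(x$direction) %||%
           paste0("NMDS", seq_along(x$direction)),
         direction = unname(x$direction))
}

#' @rdname dietlink-tidiers
#' @export
glance.vector_fit <- function(x, ...) {
  tibble(r = x$r, r2 = x$r^2, p_value = x$p_value, n_perm = x$n_perm)
}

#' @rdname dietlink-tidiers
#' @export
tidy.threshold_selection <- function(x, ...) x$diagnostics

#' @rdname dietlink-tidiers
#' @export
glance.threshold_selection <- function(x, ...) {
  best <- x$diagnostics[x$diagnostics$threshold == x$threshold, ]
  tibble(threshold = x$threshold, n_motus = best$n_motus,
         species_with_multiple_motus = best$species_with_multiple_motus,
         n_species_assignments = best$n_species_assignments)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "Prey-choice null model: %d individuals, %d iterations, %.0f%% limits\n",
    x$n_individuals, x$n_iterations, 100 * x$conf))
  cat(sprintf("Selection strength S = %.3f\n", x$selection_strength))
  print(x$table)
  invisible(x)
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("Pianka overlap: observed %.3f, null mean %.3f (%s, %d iter)\n",
              x$observed, x$null_mean, x$algorithm, x$n_iterations))
  cat(sprintf("Proportion of null overlaps exceeded: %.4f\n",
              x$proportion_exceeded))
  invisible(x)
}

#' @export
print.permanova_test <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f (df %d, %d), R2 = %.3f, p = %.4f\n",
              x$statistic, x$df[1], x$df[2], x$R2, x$p_value))
  invisible(x)
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat(sprintf("Accumulation curve (%s): S_obs = %d, Chao2 = %.2f\n",
              x$mode, x$S_obs, x$chao2))
  print(x$n_for_fraction)
  invisible(x)
}

#' @export
print.threshold_selection <- function(x, ...) {
  cat(sprintf("Optimal MOTU threshold: %.2f\n", x$threshold))
  print(x$diagnostics)
  invisible(x)
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): stress = %.4f over %d restarts\n",
              ncol(x$scores), x$stress, x$n_restarts))
  invisible(x)
}
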