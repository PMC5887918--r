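test_that("RA3 randomization conserves each row's value multiset", {
  m <- rbind(c(0.5, 0.3, 0.2, 0, 0), c(0.1, 0.1, 0.4, 0.4, 0))
  set.seed(1)
  for (i in 1:25) {
    r <- randomize_utilization(m, "RA3")
    expect_equal(sort(r[1, ]), sort(m[1, ]))
    expect_equal(sort(r[2, ]), sort(m[2, ]))
  }
  expect_identical(randomize_utilization(m, "RA3", seed = 5),
                   randomize_utilization(m, "RA3", seed = 5))
  expect_error(randomize_utilization(m, "RA9"))
})

test_that("RA2 keeps zero structure and redraws nonzero states", {
  m <- rbind(c(0.5, 0, 0.5, 0), c(0, 0.2, 0.8, 0))
  set.seed(2)
  r <- randomize_utilization(m, "RA2")
  expect_equal(r == 0, m == 0)
  expect_true(all(r[m > 0] > 0 & r[m > 0] < 1))
})

test_that("RA3 permutations are uniform over the 3! arrangements", {
  v <- c(0.5, 0.3, 0.2)
  m <- rbind(v, v)
  set.seed(3)
  draws <- replicate(10000, paste(randomize_utilization(m, "RA3")[1, ],
                                  collapse = ","))
  freq <- table(draws) / 10000
  expect_equal(length(freq), 6)
  # each of the 6 permutations at 1/6 within 4 binomial standard errors
  se <- sqrt((1 / 6) * (5 / 6) / 10000)
  expect_true(all(abs(freq - 1 / 6) < 4 * se))
})

test_that("overlap null test matches complete enumeration on 5 taxa", {
  p <- c(0.55, 0.25, 0.1, 0.06, 0.04) # strongly skewed, identical vectors
  exact_null <- enumerate_overlap_null(p, p)
  obs <- pianka_overlap(p, p)
  exact_prop <- mean(exact_null < obs)
  expect_gt(exact_prop, 0.95) # identical skewed diets overlap non-randomly

  fit <- overlap_null_test(p, p, n_iterations = 10000, seed = 11)
  expect_equal(fit$observed, 1)
  mc_se <- sqrt(exact_prop * (1 - exact_prop) / 10000)
  expect_lt(abs(fit$proportion_exceeded - exact_prop), 4 * mc_se)
  expect_lt(abs(fit$null_mean - mean(exact_null)), 0.01)
})

test_that("uniform utilization makes the observed overlap unexceedable", {
  pj <- rep(0.2, 5)
  pk <- c(0.5, 0.25, 0.125, 0.0625, 0.0625) # dyadic: permuted sums are exact
  fit <- overlap_null_test(pj, pk, n_iterations = 2000, seed = 12)
  # every RA3 arrangement gives the same overlap as observed
  expect_equal(fit$proportion_exceeded, 0)
  expect_equal(fit$proportion_above, 0)
})

test_that("overlap test is reproducible under a fixed seed and warns when shallow", {
  p <- c(0.5, 0.3, 0.2)
  q <- c(0.2, 0.3, 0.5)
  f1 <- overlap_null_test(p, q, n_iterations = 500, seed = 9)
  f2 <- overlap_null_test(p, q, n_iterations = 500, seed = 9)
  expect_equal(f1$null_overlaps, f2$null_overlaps)
  expect_equal(tidy(f1), tidy(f2))
  expect_warning(overlap_null_test(p, q, n_iterations = 50, seed = 1))
})

test_that("null consumption counts match binomial enumeration for 1-item guts", {
  ab <- c(a = 30, b = 50, c = 20)
  n_ind <- 12
  counts <- null_consumption_counts(ab, rep(1L, n_ind), 10000, seed = 21)
  expect_equal(dim(counts), c(10000, 3))
  expect_true(all(rowSums(counts) == n_ind))
  for (t in 1:3) {
    p_t <- ab[t] / sum(ab)
    mu <- n_ind * p_t
    se <- sqrt(n_ind * p_t * (1 - p_t) / 10000)
    expect_lt(abs(mean(counts[, t]) - mu), 4 * se)
    # empirical limits within one count of the exact binomial quantiles
    q_emp <- quantile(counts[, t], c(0.025, 0.975), names = FALSE)
    q_exact <- stats::qbinom(c(0.025, 0.975), n_ind, p_t)
    expect_lte(max(abs(q_emp - q_exact)), 1)
  }
})

test_that("expected null consumption is monotone in a taxon's abundance", {
  set.seed(22)
  gut_sizes <- rep(2L, 10)
  e_at <- function(a1) {
    ab <- c(x = a1, y = 40, z = 40)
    mean(null_consumption_counts(ab, gut_sizes, 4000)[, "x"])
  }
  es <- vapply(c(5, 20, 60, 120), e_at, numeric(1))
  expect_true(all(diff(es) > 0))
})

test_that("prey choice classification flags forced preference and avoidance", {
  # 10 individuals, 1 item each, two equally abundant taxa; all chose A
  dm <- tibble::tibble(
    individual_id = sprintf("i%02d", 1:10),
    predator_species = "pred", site_id = "S01", season = "S1",
    A = 1L, B = 0L)
  class(dm) <- c("diet_matrix", class(dm))
  res <- prey_choice_null(dm, c(A = 50, B = 50), n_iterations = 10000,
                          seed = 31)
  tab <- res$table
  expect_equal(tab$class[tab$taxon == "A"], "preferred")
  expect_equal(tab$class[tab$taxon == "B"], "avoided")
  # binomial(10, 0.5) oracle: 95% limits around (2, 8)
  expect_lte(abs(tab$lower[tab$taxon == "A"] - 2), 1)
  expect_lte(abs(tab$upper[tab$taxon == "A"] - 8), 1)
  expect_equal(tab$expected[tab$taxon == "A"], 5, tolerance = 0.05)
  expect_equal(res$selection_strength, selection_strength(
    c(10, 0), c(tab$expected[tab$taxon == "A"], tab$expected[tab$taxon == "B"])))

  # reproducibility
  res2 <- prey_choice_null(dm, c(A = 50, B = 50), n_iterations = 10000,
                           seed = 31)
  expect_equal(tidy(res), tidy(res2))
})

test_that("a single available taxon is degenerate and neutral", {
  dm <- tibble::tibble(
    individual_id = sprintf("i%02d", 1:6),
    predator_species = "pred", site_id = "S01", season = "S1", A = 1L)
  class(dm) <- c("diet_matrix", class(dm))
  res <- prey_choice_null(dm, c(A = 10), n_iterations = 500, seed = 32)
  expect_equal(res$table$expected, 6)
  expect_equal(res$table$lower, 6)
  expect_equal(res$table$upper, 6)
  expect_equal(res$table$class, "neutral")
})

test_that("gut sizes larger than the available taxa are rejected", {
  expect_error(null_consumption_counts(c(a = 1, b = 1), c(3L), 10),
               class = "dietlink_param_error")
  expect_error(null_consumption_counts(c(a = 0, b = 0), c(1L), 10),
               class = "dietlink_param_error")
})

test_that("per-site stratified nulls respect each site's abundance", {
  # site A only has taxon x, site B only taxon y: null counts are forced
  dm <- tibble::tibble(
    individual_id = sprintf("i%02d", 1:8),
    predator_species = "pred",
    site_id = rep(c("SA", "SB"), each = 4), season = "S1",
    x = rep(c(1L, 0L), each = 4), y = rep(c(0L, 1L), each = 4))
  class(dm) <- c("diet_matrix", class(dm))
  ab <- tibble::tibble(site_id = rep(c("SA", "SB"), each = 2),
                       taxon = rep(c("x", "y"), 2),
                       count = c(30, 0, 0, 30))
  res <- prey_choice_null(dm, ab, n_iterations = 400, seed = 33)
  expect_equal(res$table$expected, c(4, 4))
  expect_equal(res$table$class, c("neutral", "neutral"))
})

test_that("selection comparisons cross-tabulate joint preferences", {
  mk <- function(classes) {
    structure(list(table = tibble::tibble(
      taxon = paste0("t", seq_along(classes)),
      observed = 1, expected = 1, lower = 0, upper = 2,
      class = classes)), class = "selection_result")
  }
  cmp <- compare_selection(mk(c("preferred", "avoided", "neutral")),
                           mk(c("preferred", "neutral", "neutral")))
  expect_equal(cmp$jointly_preferred, "t1")
  expect_equal(cmp$jointly_avoided, character(0))
  same <- compare_selection(mk(c("preferred", "avoided")),
                            mk(c("preferred", "avoided")))
  expect_equal(same$jointly_preferred, "t1")
  expect_equal(same$jointly_avoided, "t2")
  expect_error(compare_selection(mk("neutral"), mk(c("neutral", "neutral"))),
               class = "dietlink_param_error")
})
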