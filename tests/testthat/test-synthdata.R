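test_that("reference database has the forced composition and is deterministic", {
  db1 <- generate_reference_db(2, haplotypes_per_taxon = 1, seq_length = 287,
                               between_taxon_divergence = 0.10,
                               within_taxon_divergence = 0, seed = 1)
  expect_equal(nrow(db1), 5) # 2 prey + 2 predators + 1 contaminant
  expect_equal(sum(db1$is_predator), 2)
  expect_equal(sum(db1$is_contaminant), 1)
  expect_true(all(nchar(db1$sequence) == 287))
  expect_true(all(strsplit(paste(db1$sequence, collapse = ""), "")[[1]] %in%
                    c("A", "C", "G", "T")))

  db2 <- generate_reference_db(2, haplotypes_per_taxon = 1, seq_length = 287,
                               between_taxon_divergence = 0.10,
                               within_taxon_divergence = 0, seed = 1)
  expect_identical(db1, db2)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_barcode_fasta(db1, f1)
  write_barcode_fasta(db2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # FASTA round-trip
  expect_equal(read_barcode_fasta(f1)$sequence, db1$sequence)
  expect_equal(read_barcode_fasta(f1)$taxon_id, db1$taxon_id)

  expect_error(generate_reference_db(4, between_taxon_divergence = 0.01,
                                     within_taxon_divergence = 0.05),
               class = "dietlink_param_error")
  expect_error(generate_reference_db(1), class = "dietlink_param_error")
})

test_that("generated divergences respect the within/between bounds", {
  db <- fixture_db(n_prey = 4, within = 0.01, between = 0.10, seed = 3)
  recs <- db[!db$is_contaminant, ]
  # exhaustive pairwise alignment over the small fixture
  for (i in seq_len(nrow(recs) - 1)) {
    for (j in seq((i + 1), nrow(recs))) {
      id <- pairwise_identity(recs$sequence[i], recs$sequence[j])
      if (recs$taxon_id[i] == recs$taxon_id[j]) {
        expect_gte(id, 0.97)
      } else {
        expect_lte(id, 0.93)
      }
    }
  }
})

test_that("community simulation follows the scenario", {
  sc <- community_scenario(
    sites = tibble::tibble(site_id = sprintf("S%02d", 1:10),
                           intensity = seq(0, 2, length.out = 10)),
    taxa = tibble::tibble(
      taxon_id = c("flat", "up", "down"),
      response = c("flat", "increasing", "decreasing"),
      baseline_abundance = c(100, 50, 50),
      response_slope = c(0, 1, 4)))
  # degenerate noise: flat taxon gives its baseline everywhere
  ab0 <- simulate_community(sc, noise_dispersion = 0, seed = 1)
  expect_true(all(ab0$count[ab0$taxon_id == "flat"] == 100))

  # increasing taxon: median Spearman correlation with intensity > 0
  rho <- replicate(100, {
    ab <- simulate_community(sc, noise_dispersion = 0.3)
    up <- ab[ab$taxon_id == "up", ]
    suppressWarnings(cor(up$count, up$intensity, method = "spearman"))
  })
  expect_gt(median(rho), 0)

  # strongly decreasing taxon: usually extinct at the top site
  top_zero <- replicate(100, {
    ab <- simulate_community(sc, noise_dispersion = 0.3)
    ab$count[ab$taxon_id == "down" & ab$site_id == "S10"] == 0
  })
  expect_gt(mean(top_zero), 0.5)

  # overdispersion contract: variance >= mean across replicates
  reps <- replicate(200, {
    simulate_community(sc, noise_dispersion = 0.5)$count[1]
  })
  expect_gte(stats::var(reps), mean(reps) * 0.8) # NB: var = mu + 0.5 mu^2
})

test_that("gut simulation draws by abundance x weight and excludes self", {
  # one taxon present: every gut contains exactly it
  g <- simulate_guts(c(a = 10, pred = 5), "pred", 20, items_per_gut = 1,
                     seed = 1)
  expect_true(all(vapply(g$consumed, identical, logical(1), "a")))

  # binomial oracle: two equal taxa, weight ratio 9:1, 1 item per gut
  set.seed(7)
  g <- simulate_guts(c(a = 50, b = 50), "pred", 1000, items_per_gut = 1,
                     selection_weights = c(a = 9, b = 1))
  frac_a <- mean(vapply(g$consumed, function(x) "a" %in% x, logical(1)))
  expect_lt(abs(frac_a - 0.9), 3 * sqrt(0.9 * 0.1 / 1000))

  # own taxon never consumed even with positive abundance
  g <- simulate_guts(c(a = 5, b = 5, pred = 100), "pred", 200, seed = 2)
  expect_false(any(vapply(g$consumed, function(x) "pred" %in% x, logical(1))))

  expect_error(simulate_guts(c(pred = 10), "pred", 5),
               class = "dietlink_param_error")
  expect_identical(simulate_guts(c(a = 1, b = 2), "p", 10, seed = 9),
                   simulate_guts(c(a = 1, b = 2), "p", 10, seed = 9))
})

test_that("zero-truncated Poisson gut sizes have the configured mean", {
  set.seed(5)
  k <- dietlink:::rztpois(20000, 4.5)
  expect_true(all(k >= 1))
  expect_lt(abs(mean(k) - 4.5), 0.05)
})

test_that("read simulation conserves counts, truth and MID design", {
  db <- fixture_db(n_prey = 4, seed = 11)
  ab <- stats::setNames(rep(20, 4), unique(db$taxon_id)[1:4])
  guts <- simulate_guts(ab, "Rhyacophila.dorsalis", 12, seed = 12)
  sim <- simulate_reads(guts, db, mid_design = c(4, 3), reads_per_gut = 30,
                        seed = 13)
  expect_equal(nrow(sim$reads), 30 * 12)
  expect_setequal(sim$truth$read_id, sim$reads$read_id)
  expect_equal(nrow(sim$mid_map), 12)

  # a 16 x 15 MID design registers exactly 240 unique pairs
  map <- make_mid_map(16, 15, seed = 1)
  expect_equal(nrow(map), 240)
  expect_equal(nrow(dplyr::distinct(map, forward_mid, reverse_mid)), 240)

  # error-free, artefact-free reads are exact templates of consumed taxa
  clean <- simulate_reads(guts, db, mid_design = c(4, 3), reads_per_gut = 20,
                          error_rate = 0, chimera_rate = 0,
                          predator_dna_fraction = 0, contaminant_fraction = 0,
                          seed = 14)
  demux <- demultiplex(clean$reads, clean$mid_map)
  joined <- dplyr::inner_join(demux, clean$truth, by = "read_id")
  expect_true(all(joined$individual_id.x == joined$individual_id.y))
  expect_true(all(joined$category == "prey"))
  key <- paste(joined$taxon_id, joined$sequence)
  dbkey <- paste(db$taxon_id, db$sequence)
  expect_true(all(key %in% dbkey))
  # and each read's taxon was truly consumed by its gut
  consumed <- stats::setNames(guts$consumed, guts$individual_id)
  ok <- mapply(function(t, i) t %in% consumed[[i]],
               joined$taxon_id, joined$individual_id.x)
  expect_true(all(ok))

  # too few MID combinations is a configuration error
  expect_error(simulate_reads(guts, db, mid_design = c(3, 3)),
               class = "dietlink_config_error")

  # determinism: identical seeds give byte-identical FASTA
  sim2 <- simulate_reads(guts, db, mid_design = c(4, 3), reads_per_gut = 30,
                         seed = 13)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(sim$reads, f1)
  write_fasta(sim2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("predator self-DNA fraction lands in its binomial band", {
  db <- fixture_db(n_prey = 4, seed = 21)
  ab <- stats::setNames(rep(20, 4), unique(db$taxon_id)[1:4])
  guts <- simulate_guts(ab, "Dinocras.cephalotes", 50, seed = 22)
  sim <- simulate_reads(guts, db, mid_design = c(10, 5), reads_per_gut = 200,
                        predator_dna_fraction = 0.03, seed = 23)
  n_pred <- sum(sim$truth$category == "predator")
  band <- stats::qbinom(c(0.005, 0.995), 10000, 0.03)
  expect_gte(n_pred, band[1])
  expect_lte(n_pred, band[2])
})

test_that("MID tags respect the minimum Hamming distance", {
  tags <- design_mids(16, length = 10, min_dist = 3, seed = 2)
  expect_equal(length(tags), 16)
  expect_true(all(nchar(tags) == 10))
  d <- outer(tags, tags, Vectorize(function(a, b) sum(hamming(a, b))))
  expect_true(all(d[upper.tri(d)] >= 3))
})
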