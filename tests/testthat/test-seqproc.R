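mk_reads <- function(...) tibble::tibble(read_id = sprintf("r%d", seq_along(c(...))),
                                         sequence = c(...))

test_that("demultiplexing assigns by exact MID pair and trims to template", {
  fp <- "ACGTAC"; rp <- "GGTTCC"
  map <- tibble::tibble(forward_mid = c("AAAAA", "CCCCC"),
                        reverse_mid = c("GGGGG", "TTTTT"),
                        individual_id = c("ind1", "ind2"))
  tpl <- strrep("ACGT", 10)
  read1 <- paste0("AAAAA", fp, tpl, revcomp(paste0("GGGGG", rp)))
  readx <- paste0("AGAAA", fp, tpl, revcomp(paste0("GGGGG", rp)))
  out <- demultiplex(mk_reads(read1, readx), map, fwd_primer = fp,
                     rev_primer = rp)
  expect_equal(out$individual_id, c("ind1", NA))
  expect_equal(out$sequence[1], tpl)
  # one mismatch tolerated when allowed
  out1 <- demultiplex(mk_reads(readx), map, max_mismatch = 1,
                      fwd_primer = fp, rev_primer = rp)
  expect_equal(out1$individual_id, "ind1")

  dup <- dplyr::bind_rows(map, map[1, ])
  expect_error(demultiplex(mk_reads(read1), dup),
               class = "dietlink_config_error")
})

test_that("simulated error-free batches demultiplex to their true individuals", {
  db <- fixture_db(n_prey = 4, seed = 31)
  ab <- stats::setNames(rep(10, 4), unique(db$taxon_id)[1:4])
  guts <- simulate_guts(ab, "Rhyacophila.dorsalis", 10, seed = 32)
  sim <- simulate_reads(guts, db, mid_design = c(5, 2), reads_per_gut = 40,
                        seed = 33)
  out <- demultiplex(sim$reads, sim$mid_map)
  truth <- sim$truth[match(out$read_id, sim$truth$read_id), ]
  expect_true(all(!is.na(out$individual_id)))
  expect_equal(out$individual_id, truth$individual_id)
})

test_that("length filter keeps the inclusive 260-300 window", {
  reads <- tibble::tibble(read_id = as.character(1:4),
                          sequence = strrep("A", c(259, 260, 300, 301)))
  kept <- length_filter(reads)
  expect_equal(nchar(kept$sequence), c(260, 300))
  expect_equal(nrow(length_filter(reads[0, ])), 0)
  expect_error(length_filter(reads, 300, 260), class = "dietlink_param_error")
})

test_that("haplotype collapse counts copies and drops rare variants", {
  reads <- tibble::tibble(
    individual_id = "i1",
    sequence = c(rep("AAA", 3), "AAT"))
  h <- collapse_haplotypes(reads, min_copies = 2)
  expect_equal(h$sequence, "AAA")
  expect_equal(h$copy_count, 3)

  reads2 <- tibble::tibble(individual_id = "i1",
                           sequence = rep(c("AAA", "AAT"), each = 2))
  expect_equal(nrow(collapse_haplotypes(reads2)), 2)

  singles <- tibble::tibble(individual_id = "i1",
                            sequence = c("AAA", "AAT", "ATT"))
  expect_equal(nrow(collapse_haplotypes(singles)), 0)
})

test_that("pairwise identity matches hand-derived values and is symmetric", {
  a <- strrep("A", 100)
  expect_equal(pairwise_identity(a, a), 1.0)
  b <- paste0(strrep("A", 95), strrep("C", 5))
  expect_equal(pairwise_identity(a, b), 0.95) # no-gap optimum, 5 mismatches
  set.seed(1)
  for (i in 1:5) {
    x <- dietlink:::random_seq(60)
    y <- dietlink:::random_seq(55)
    expect_equal(pairwise_identity(x, y), pairwise_identity(y, x))
  }
  expect_error(pairwise_identity("", "ACGT"), class = "dietlink_param_error")
})

test_that("clustering splits or merges a pair exactly at the threshold", {
  set.seed(4)
  s1 <- dietlink:::random_seq(100)
  s2 <- dietlink:::mutate_positions(s1, 10) # identity 0.90 (no-gap optimum)
  expect_equal(pairwise_identity(s1, s2), 0.90)
  haps <- tibble::tibble(individual_id = c("i1", "i2"),
                         sequence = c(s1, s2), copy_count = c(5, 3))
  expect_equal(nrow(cluster_motus(haps, 0.89)$representatives), 1)
  expect_equal(nrow(cluster_motus(haps, 0.92)$representatives), 2)

  one <- haps[1, ]
  m1 <- cluster_motus(one, 0.95)
  expect_equal(nrow(m1$representatives), 1)
  expect_equal(m1$representatives$sequence, s1)

  # invariance to input row order
  m_fwd <- cluster_motus(haps, 0.92)
  m_rev <- cluster_motus(haps[2:1, ], 0.92)
  expect_equal(m_fwd$representatives, m_rev$representatives)
})

test_that("MOTU count is non-increasing as the threshold decreases", {
  db <- fixture_db(n_prey = 5, within = 0.03, between = 0.12, seed = 41)
  haps <- db_haplotypes(db)
  grid <- seq(0.97, 0.87, by = -0.01)
  n <- vapply(grid, function(t) nrow(cluster_motus(haps, t)$representatives),
              numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("greedy clustering matches the brute-force reference on small sets", {
  set.seed(8)
  for (rep in 1:4) {
    base <- dietlink:::random_seq(80)
    seqs <- c(base, vapply(1:7, function(i)
      dietlink:::mutate_positions(base, sample(c(2, 6, 12, 25), 1)),
      character(1)))
    haps <- tibble::tibble(individual_id = sprintf("i%d", 1:8),
                           sequence = seqs,
                           copy_count = sample(1:9, 8, replace = TRUE))
    for (t in c(0.97, 0.92, 0.88)) {
      ours <- cluster_motus(haps, t)
      ref <- brute_force_clusters(haps, t)
      # same clusters: membership partition and centroid sequences agree
      ours_members <- split(ours$members$sequence, ours$members$motu_id)
      ref_members <- split(ref$sequence, ref$assignment)
      expect_equal(length(ours_members), length(ref_members))
      expect_setequal(ours$representatives$sequence, ref$centroids)
      norm <- function(x) unname(lapply(x, function(s) sort(unique(s))))
      expect_setequal(lapply(norm(ours_members), paste, collapse = "|"),
                      lapply(norm(ref_members), paste, collapse = "|"))
    }
  }
})

test_that("taxonomy assignment applies the >98% best-hit consensus rules", {
  db <- fixture_db(n_prey = 6, seed = 51)
  # exact barcode -> that species at identity 1
  rep1 <- db$sequence[1]
  a <- assign_taxonomy(rep1, db)
  expect_equal(a$rank, "species")
  expect_equal(a$taxon, db$species_label[1])
  expect_equal(a$identity, 1.0)

  # ~5% divergent from everything -> no_match
  far <- dietlink:::mutate_positions(db$sequence[1], 15)
  expect_equal(assign_taxonomy(far, db)$rank, "no_match")

  # near-identical to the contaminant record -> contaminant
  cont <- db$sequence[db$is_contaminant][1]
  near_cont <- dietlink:::mutate_positions(cont, 2)
  expect_equal(assign_taxonomy(near_cont, db)$rank, "contaminant")

  # equidistant between two congeneric species -> genus-level consensus
  sp <- tibble::tibble(
    taxon_id = c("x1", "x2"), species_label = c("Genus_x_sp1", "Genus_x_sp2"),
    genus = "Genus_x", family = "Family_x", order = "Invertebrata",
    rank = "species", haplotype = 1L,
    sequence = NA_character_, is_predator = FALSE, is_contaminant = FALSE)
  set.seed(9)
  s1 <- dietlink:::random_seq(200)
  ch <- strsplit(s1, "")[[1]]
  pos <- sample.int(200, 4)
  ch2 <- ch
  for (p in pos) ch2[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  s2 <- paste(ch2, collapse = "")
  chq <- ch
  for (p in pos[1:2]) chq[p] <- ch2[p]
  q <- paste(chq, collapse = "")
  sp$sequence <- c(s1, s2)
  aq <- assign_taxonomy(q, sp)
  expect_equal(aq$rank, "genus")
  expect_equal(aq$taxon, "Genus_x")
})

test_that("threshold selection scans the grid and applies the optimality rule", {
  # tight taxa: every threshold resolves species uniquely; tie-break -> 0.97
  db <- fixture_db(n_prey = 5, within = 0.01, between = 0.10, seed = 61)
  haps <- db_haplotypes(db[!db$is_contaminant, ])
  sel <- select_threshold(haps, db)
  expect_equal(sel$threshold, 0.97)
  expect_true(all(sel$diagnostics$species_with_multiple_motus == 0))
  expect_equal(nrow(sel$diagnostics), 11)
  expect_equal(sel$diagnostics$threshold, seq(0.97, 0.87, by = -0.01))

  # divergent haplotypes: multi-MOTU species count non-increasing with t
  db8 <- fixture_db(n_prey = 5, within = 0.08, between = 0.25, seed = 62)
  haps8 <- db_haplotypes(db8[!db8$is_contaminant, ])
  sel8 <- select_threshold(haps8, db8)
  expect_true(all(diff(sel8$diagnostics$species_with_multiple_motus) <= 0))
  # conspecific haplotypes merge once t drops below their identity
  expect_gt(max(sel8$diagnostics$species_with_multiple_motus), 0)

  # single haplotype: highest threshold wins, one species assignment
  solo <- db_haplotypes(db[1, ])
  sel1 <- select_threshold(solo, db)
  expect_equal(sel1$threshold, 0.97)
  expect_true(all(sel1$diagnostics$n_motus == 1))
  expect_true(all(sel1$diagnostics$species_with_multiple_motus == 0))
  expect_true(all(sel1$diagnostics$n_species_assignments == 1))

  expect_error(select_threshold(haps[0, ], db), class = "dietlink_param_error")
})

test_that("chimeric representatives are flagged by the split-hit heuristic", {
  db <- fixture_db(n_prey = 6, within = 0, between = 0.15, seed = 71)
  s1 <- db$sequence[db$taxon_id == "t01"][1]
  s2 <- db$sequence[db$taxon_id == "t02"][1]
  chim <- paste0(substr(s1, 1, 143), substr(s2, 144, 287))
  expect_true(dietlink:::is_chimeric(chim, db))
  expect_false(dietlink:::is_chimeric(s1, db))
})
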