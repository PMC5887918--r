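#' Generate a synthetic barcode reference database
#'
#' Builds a small CO1-style barcode reference with known structure: a
#' configurable number of prey taxa, two predator taxa (a caddisfly and a
#' stonefly, the intraguild pair the pipeline is designed around) and at
#' least one contaminant record (human). Each prey/predator taxon is
#' derived from a common ancestral sequence mutated at
#' `between_taxon_divergence` of its positions; haplotypes within a taxon
#' are the taxon reference mutated at `within_taxon_divergence` of
#' positions. Pairwise identities therefore satisfy (approximately, and
#' verified exactly on fixtures by alignment): within-taxon identity >=
#' 1 - 2*within, between-taxon identity <= 1 - between.
#'
#' @param n_prey_taxa number of prey taxa (>= 2).
#' @param haplotypes_per_taxon barcode records per prey/predator taxon.
#' @param seq_length barcode length in bp (marker fragment is ~287 bp).
#' @param between_taxon_divergence,within_taxon_divergence per-site
#'   divergence fractions; must satisfy 0 <= within < between <= 0.3.
#' @param seed integer seed; identical seeds give identical databases.
#' @return a tibble of class `barcode_db` with columns `taxon_id`,
#'   `species_label`, `genus`, `family`, `order`, `rank`, `haplotype`,
#'   `sequence`, `is_predator`, `is_contaminant`.
#' @examples
#' db <- generate_reference_db(4, seed = 1)
#' dplyr::count(db, is_predator, is_contaminant)
#' @export
generate_reference_db <- function(n_prey_taxa,
                                  haplotypes_per_taxon = 2,
                                  seq_length = 287,
                                  between_taxon_divergence = 0.15,
                                  within_taxon_divergence = 0.01,
                                  seed = NULL) {
  if (n_prey_taxa < 2) {
    abort("n_prey_taxa must be >= 2", class = "dietlink_param_error")
  }
  if (!(within_taxon_divergence >= 0 &&
        within_taxon_divergence < between_taxon_divergence &&
        between_taxon_divergence <= 0.3)) {
    abort("need 0 <= within < between <= 0.3 divergence",
          class = "dietlink_param_error")
  }
  maybe_with_seed(seed, {
    ancestor <- random_seq(seq_length)
    k_between <- max(1L, round(between_taxon_divergence * seq_length))
    k_within <- round(within_taxon_divergence * seq_length)

    prey_ids <- sprintf("t%02d", seq_len(n_prey_taxa))
    pred_ids <- c("Rhyacophila.dorsalis", "Dinocras.cephalotes")
    taxa <- tibble(
      taxon_id = c(prey_ids, pred_ids),
      species_label = c(sprintf("Prey_species_%02d", seq_len(n_prey_taxa)),
                        pred_ids),
      genus = c(sprintf("Genus_%02d", ceiling(seq_len(n_prey_taxa) / 2)),
                "Rhyacophila", "Dinocras"),
      family = c(sprintf("Family_%d", ceiling(seq_len(n_prey_taxa) / 4)),
                 "Rhyacophilidae", "Perlidae"),
      order = "Invertebrata",
      is_predator = c(rep(FALSE, n_prey_taxa), TRUE, TRUE),
      is_contaminant = FALSE
    )
    taxa$reference <- vapply(seq_len(nrow(taxa)), function(i) {
      mutate_positions(ancestor, k_between)
    }, character(1))

    recs <- purrr::pmap(taxa, function(taxon_id, species_label, genus, family,
                                       order, is_predator, is_contaminant,
                                       reference) {
      haps <- c(reference,
                vapply(seq_len(max(0L, haplotypes_per_taxon - 1L)),
                       function(h) mutate_positions(reference, k_within),
                       character(1)))
      tibble(taxon_id, species_label, genus, family, order,
             rank = "species", haplotype = seq_along(haps), sequence = haps,
             is_predator, is_contaminant)
    }) |> list_rbind()

    contaminant <- tibble(
      taxon_id = "Homo.sapiens", species_label = "Homo.sapiens",
      genus = "Homo", family = "Hominidae", order = "Contaminant",
      rank = "species", haplotype = 1L,
      sequence = mutate_positions(ancestor,
                                  max(k_between, round(0.28 * seq_length))),
      is_predator = FALSE, is_contaminant = TRUE
    )
    out <- bind_rows(recs, contaminant)
    class(out) <- c("barcode_db", class(out))
    out
  })
}

#' Write / read a barcode database as FASTA
#'
#' Headers use the form `taxon_id|species_label|genus|family|order|rank|
#' haplotype|flags` so a database round-trips through FASTA.
#'
#' @param db a `barcode_db` tibble.
#' @param path FASTA path.
#' @export
write_barcode_fasta <- function(db, path) {
  flags <- paste0(ifelse(db$is_predator, "P", ""),
                  ifelse(db$is_contaminant, "C", ""))
  hdr <- paste(db$taxon_id, db$species_label, db$genus, db$family, db$order,
               db$rank, db$haplotype, flags, sep = "|")
  write_fasta(tibble(read_id = hdr, sequence = db$sequence), path)
}

#' @rdname write_barcode_fasta
#' @export
read_barcode_fasta <- function(path) {
  x <- read_fasta(path)
  parts <- stringr::str_split_fixed(x$read_id, stringr::fixed("|"), 8)
  out <- tibble(
    taxon_id = parts[, 1], species_label = parts[, 2], genus = parts[, 3],
    family = parts[, 4], order = parts[, 5], rank = parts[, 6],
    haplotype = as.integer(parts[, 7]), sequence = x$sequence,
    is_predator = grepl("P", parts[, 8], fixed = TRUE),
    is_contaminant = grepl("C", parts[, 8], fixed = TRUE)
  )
  class(out) <- c("barcode_db", class(out))
  out
}

#' Describe a prey-community scenario along an intensity gradient
#'
#' A scenario bundles sites (with an agricultural-intensity score), taxa
#' (with a direction and slope of response to intensity) and season
#' labels. Expected abundance of taxon j at site i is
#' `baseline * exp(dir * slope * intensity)` with `dir` +1 for
#' increasing, -1 for decreasing and 0 for flat responders, emulating
#' community turnover along a land-use gradient.
#'
#' @param sites tibble with `site_id`, `intensity`.
#' @param taxa tibble with `taxon_id`, `response`
#'   (increasing/decreasing/flat), `baseline_abundance`, `response_slope`.
#' @param seasons character vector of season labels.
#' @return a list of class `community_scenario`.
#' @export
community_scenario <- function(sites, taxa, seasons = "S1") {
  stopifnot(all(c("site_id", "intensity") %in% names(sites)),
            all(c("taxon_id", "response", "baseline_abundance",
                  "response_slope") %in% names(taxa)))
  bad <- setdiff(taxa$response, c("increasing", "decreasing", "flat"))
  if (length(bad)) {
    abort(paste("unknown response type:", paste(bad, collapse = ", ")),
          class = "dietlink_param_error")
  }
  if (any(taxa$baseline_abundance < 0)) {
    abort("baseline_abundance must be nonnegative",
          class = "dietlink_param_error")
  }
  structure(list(sites = as_tibble(sites), taxa = as_tibble(taxa),
                 seasons = seasons),
            class = "community_scenario")
}

scenario_mean <- function(scenario) {
  dir <- c(increasing = 1, decreasing = -1, flat = 0)
  tidyr::expand_grid(scenario$sites, scenario$taxa) |>
    mutate(mu = .data$baseline_abundance *
             exp(dir[.data$response] * .data$response_slope * .data$intensity))
}

#' Simulate kick-sample count tables from a community scenario
#'
#' Draws overdispersed (negative-binomial) counts per site, season and
#' taxon around the scenario's expected abundances; `noise_dispersion`
#' is the NB dispersion (variance = mu + dispersion * mu^2, so variance
#' >= mean always). `noise_dispersion = 0` is the degenerate noise-free
#' limit: counts are the rounded expectations.
#'
#' @param scenario a [community_scenario()].
#' @param noise_dispersion nonnegative NB dispersion.
#' @param seed integer seed.
#' @return tibble with `site_id`, `season`, `intensity`, `taxon_id`,
#'   `count`.
#' @export
simulate_community <- function(scenario, noise_dispersion = 0.2, seed = NULL) {
  stopifnot(inherits(scenario, "community_scenario"), noise_dispersion >= 0)
  mu_tab <- scenario_mean(scenario)
  maybe_with_seed(seed, {
    out <- tidyr::expand_grid(season = scenario$seasons, mu_tab)
    out$count <- if (noise_dispersion == 0) {
      as.integer(round(out$mu))
    } else {
      rnbinom(nrow(out), mu = out$mu, size = 1 / noise_dispersion)
    }
    out |>
      select("site_id", "season", "intensity", "taxon_id", "count") |>
      arrange(.data$site_id, .data$season, .data$taxon_id)
  })
}

#' Simulate predator gut contents from local prey abundance
#'
#' Each individual consumes a number of distinct prey taxa drawn from an
#' items-per-gut distribution (default: zero-truncated Poisson with mean
#' 4.5 detected taxa per individual). Taxa enter the gut by successive
#' weighted sampling without replacement with inclusion weight
#' proportional to `abundance * selection_weight`; with all weights 1
#' this is exactly the proportional-consumption null model that the
#' prey-choice inference tests against. A predator never "consumes" its
#' own species (cannibalism is molecularly unresolvable), so its own
#' taxon is removed before renormalisation.
#'
#' @param abundance named nonnegative numeric vector of taxon counts at
#'   one site-season (names are taxon ids; may include the predator).
#' @param predator_species taxon id of the predator.
#' @param n_individuals number of guts to simulate.
#' @param items_per_gut either a single integer (fixed gut size) or a
#'   list `list(dist = "ztpois", mean = 4.5)`.
#' @param selection_weights named positive multipliers on relative
#'   abundance; missing taxa default to 1 (the null).
#' @param site_id,season metadata carried into the output.
#' @param seed integer seed.
#' @return tibble of class `gut_truth` with `individual_id`,
#'   `predator_species`, `site_id`, `season`, `n_items` and a `consumed`
#'   list-column of taxon ids.
#' @export
simulate_guts <- function(abundance, predator_species, n_individuals,
                          items_per_gut = list(dist = "ztpois", mean = 4.5),
                          selection_weights = NULL,
                          site_id = NA_character_, season = NA_character_,
                          seed = NULL) {
  if (is.null(names(abundance))) {
    abort("abundance must be a named vector", class = "dietlink_param_error")
  }
  avail <- abundance[names(abundance) != predator_species]
  if (sum(avail) <= 0) {
    abort("no available prey abundance", class = "dietlink_param_error")
  }
  w <- rep(1, length(avail))
  names(w) <- names(avail)
  if (!is.null(selection_weights)) {
    if (any(selection_weights <= 0)) {
      abort("selection weights must be positive", class = "dietlink_param_error")
    }
    hit <- intersect(names(selection_weights), names(w))
    w[hit] <- selection_weights[hit]
  }
  prob <- avail * w
  n_avail <- sum(prob > 0)
  maybe_with_seed(seed, {
    k <- draw_gut_sizes(items_per_gut, n_individuals)
    k <- pmin(k, n_avail)
    consumed <- lapply(k, function(ki) {
      names(prob)[sample_distinct(prob, ki)]
    })
    out <- tibble(
      individual_id = sprintf("%s_%s_%03d", predator_species,
                              ifelse(is.na(site_id), "x", site_id),
                              seq_len(n_individuals)),
      predator_species = predator_species,
      site_id = site_id, season = season,
      n_items = k, consumed = consumed
    )
    attr(out, "selection_weights") <- w
    class(out) <- c("gut_truth", class(out))
    out
  })
}

draw_gut_sizes <- function(spec, n) {
  if (is.numeric(spec) && length(spec) == 1L) {
    return(rep(as.integer(spec), n))
  }
  if (is.list(spec) && identical(spec$dist, "ztpois")) {
    return(rztpois(n, spec$mean))
  }
  if (is.function(spec)) return(as.integer(spec(n)))
  abort("unrecognised items_per_gut specification",
        class = "dietlink_param_error")
}

#' Design multiplex identifier (MID) tags and their pairing registry
#'
#' `design_mids()` greedily builds `n` tags of the given length with
#' pairwise Hamming distance >= `min_dist` (default 3, which makes
#' exact-match demultiplexing safe at low error rates).
#' `make_mid_map()` crosses `n_forward` x `n_reverse` tag sets into the
#' registry of unique (forward, reverse) pairs used to identify
#' individuals in pooled data; a 16 x 15 design yields 240 assignable
#' combinations.
#'
#' @param n,n_forward,n_reverse number of tags per direction.
#' @param length tag length in bp.
#' @param min_dist minimum pairwise Hamming distance within a tag set.
#' @param individual_ids optional ids to assign to the first pairs.
#' @param seed integer seed.
#' @return `design_mids()` a character vector; `make_mid_map()` a tibble
#'   `(forward_mid, reverse_mid, individual_id)`.
#' @export
design_mids <- function(n, length = 10, min_dist = 3, seed = NULL) {
  maybe_with_seed(seed, {
    tags <- character(0)
    tries <- 0L
    while (base::length(tags) < n) {
      cand <- random_seq(length)
      if (base::length(tags) == 0L || all(hamming(tags, cand) >= min_dist)) {
        tags <- c(tags, cand)
      }
      tries <- tries + 1L
      if (tries > 50000L) {
        abort("could not design enough MIDs; relax min_dist",
              class = "dietlink_config_error")
      }
    }
    tags
  })
}

#' @rdname design_mids
#' @export
make_mid_map <- function(n_forward, n_reverse, individual_ids = NULL,
                         length = 10, min_dist = 3, seed = NULL) {
  maybe_with_seed(seed, {
    fwd <- design_mids(n_forward, length, min_dist)
    rev <- design_mids(n_reverse, length, min_dist)
    map <- tidyr::expand_grid(forward_mid = fwd, reverse_mid = rev)
    map$individual_id <- NA_character_
    if (!is.null(individual_ids)) {
      if (base::length(individual_ids) > nrow(map)) {
        abort(sprintf("MID design provides %d combinations for %d individuals",
                      nrow(map), base::length(individual_ids)),
              class = "dietlink_config_error")
      }
      map$individual_id[seq_along(individual_ids)] <- individual_ids
    }
    map
  })
}

# default Folmer-region CO1 primer pair used by the read simulator
DEFAULT_FWD_PRIMER <- "GGTCAACAAATCATAAAGATATTGG"
DEFAULT_REV_PRIMER <- "ACTTATATTGTTTATACGAGGGAA"

#' Simulate multiplexed amplicon reads from gut contents
#'
#' Every read is `forward MID + forward primer + template +
#' revcomp(reverse primer) + revcomp(reverse MID)`. Templates are drawn
#' from the consumed taxa of the read's gut (uniformly over consumed
#' taxa, then over that taxon's barcode haplotypes), with configurable
#' fractions of predator self-DNA and contaminant reads, single-breakpoint
#' chimeras between two gut templates, and iid substitution errors. A
#' sidecar truth table maps every read to its gut and template taxon.
#'
#' @param guts a [simulate_guts()] result (rows = individuals).
#' @param db a `barcode_db`.
#' @param mid_design `c(n_forward, n_reverse)`; the implied number of
#'   MID pairs must be >= the number of guts.
#' @param reads_per_gut reads generated per individual.
#' @param error_rate per-base substitution probability.
#' @param chimera_rate fraction of prey reads replaced by chimeras.
#' @param predator_dna_fraction fraction of reads from the predator's
#'   own barcode (~3% in real gut-content runs).
#' @param contaminant_fraction fraction of reads from contaminant records.
#' @param fwd_primer,rev_primer primer sequences flanking the template.
#' @param seed integer seed.
#' @return list of class `read_sim`: `reads` (`read_id`, `sequence`),
#'   `truth` (`read_id`, `individual_id`, `category`, `taxon_id`),
#'   `mid_map`, and `primers`.
#' @export
simulate_reads <- function(guts, db, mid_design = c(16, 15),
                           reads_per_gut = 200,
                           error_rate = 0, chimera_rate = 0,
                           predator_dna_fraction = 0,
                           contaminant_fraction = 0,
                           fwd_primer = DEFAULT_FWD_PRIMER,
                           rev_primer = DEFAULT_REV_PRIMER,
                           seed = NULL) {
  n_guts <- nrow(guts)
  if (prod(mid_design) < n_guts) {
    abort(sprintf("MID design %dx%d cannot label %d individuals",
                  mid_design[1], mid_design[2], n_guts),
          class = "dietlink_config_error")
  }
  stopifnot(predator_dna_fraction + contaminant_fraction <= 1)
  db_by_taxon <- split(db$sequence, db$taxon_id)
  contaminants <- db$sequence[db$is_contaminant]

  maybe_with_seed(seed, {
    mid_map <- make_mid_map(mid_design[1], mid_design[2],
                            individual_ids = guts$individual_id)
    assigned <- mid_map[!is.na(mid_map$individual_id), ]
    rows <- purrr::pmap(
      list(guts$individual_id, guts$predator_species, guts$consumed,
           assigned$forward_mid, assigned$reverse_mid),
      function(ind, pred, consumed, fmid, rmid) {
        cat_draw <- sample(c("predator", "contaminant", "prey"), reads_per_gut,
                           replace = TRUE,
                           prob = c(predator_dna_fraction, contaminant_fraction,
                                    1 - predator_dna_fraction - contaminant_fraction))
        is_chim <- cat_draw == "prey" & runif(reads_per_gut) < chimera_rate
        cat_draw[is_chim] <- "chimera"
        tpl <- character(reads_per_gut)
        taxon <- rep(NA_character_, reads_per_gut)
        pool <- c(consumed)  # taxa whose templates can seed a chimera
        for (i in seq_len(reads_per_gut)) {
          tpl[i] <- switch(
            cat_draw[i],
            predator = sample_one(db_by_taxon[[pred]]),
            contaminant = sample_one(contaminants),
            prey = {
              taxon[i] <- sample_one(consumed)
              sample_one(db_by_taxon[[taxon[i]]])
            },
            chimera = {
              t2 <- sample(pool, 2, replace = length(pool) < 2)
              a <- sample_one(db_by_taxon[[t2[1]]])
              b <- sample_one(db_by_taxon[[t2[2]]])
              bp <- sample.int(min(nchar(a), nchar(b)) - 1L, 1L)
              paste0(substr(a, 1, bp), substr(b, bp + 1L, nchar(b)))
            })
          if (cat_draw[i] == "predator") taxon[i] <- pred
        }
        reads <- paste0(fmid, fwd_primer, tpl, revcomp(paste0(rmid, rev_primer)))
        tibble(individual_id = ind, category = cat_draw, taxon_id = taxon,
               sequence = reads)
      }) |> list_rbind()
    rows$sequence <- apply_substitution_errors(rows$sequence, error_rate)
    rows$read_id <- sprintf("read%06d", seq_len(nrow(rows)))
    structure(list(
      reads = rows[, c("read_id", "sequence")],
      truth = rows[, c("read_id", "individual_id", "category", "taxon_id")],
      mid_map = mid_map,
      primers = list(fwd = fwd_primer, rev = rev_primer)
    ), class = "read_sim")
  })
}

sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
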