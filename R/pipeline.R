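#' Read and validate a pipeline run configuration
#'
#' Configurations are nested lists, serialisable to JSON (or YAML when
#' the yaml package is installed); [run_pipeline()] consumes them. A
#' config either carries a `simulate` block describing the synthetic
#' scenario, or an `inputs` block pointing at existing reads, MID map,
#' barcode FASTA and abundance TSV files.
#'
#' @param path a `.json`, `.yaml` or `.yml` file.
#' @return the configuration list (validated).
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("yaml package required for YAML configs",
            class = "dietlink_config_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg configuration list.
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$out_dir)) {
    abort("config needs out_dir", class = "dietlink_config_error")
  }
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    abort("config needs a simulate block or an inputs block",
          class = "dietlink_config_error")
  }
  if (is.null(cfg$simulate)) {
    needed <- c("reads", "mids", "db", "abundance")
    missing <- needed[!vapply(needed, function(f)
      !is.null(cfg$inputs[[f]]) && file.exists(cfg$inputs[[f]]), logical(1))]
    if (length(missing)) {
      abort(paste("missing input files:", paste(missing, collapse = ", ")),
            class = "dietlink_config_error")
    }
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$seqproc <- utils::modifyList(
    list(grid_from = 0.97, grid_to = 0.87, grid_by = 0.01, min_copies = 2,
         min_len = 260, max_len = 300, max_mismatch = 0), cfg$seqproc %||% list())
  cfg$analysis <- utils::modifyList(
    list(n_iterations = 10000, conf = 0.95), cfg$analysis %||% list())
  cfg
}

#' Default synthetic scenario block
#'
#' The stated world of the simulator: a 10-site agricultural-intensity
#' gradient, 12 prey taxa with mixed responses, one season, 5
#' individuals per predator per site, 200 reads per gut, ~3% predator
#' self-DNA and 1% contaminant reads, with the stonefly predator absent
#' from the two most intensive sites.
#'
#' @return a list usable as the `simulate` block of a run config.
#' @export
default_simulate_block <- function() {
  list(n_prey_taxa = 12, haplotypes_per_taxon = 2, seq_length = 287,
       between_taxon_divergence = 0.15, within_taxon_divergence = 0.01,
       n_sites = 10, seasons = "S1", individuals_per_site = 5,
       baseline_abundance = 60, response_slope = 0.8,
       noise_dispersion = 0.2, intraguild_abundance = 5,
       predator2_absent_sites = 2,
       mid_design = c(16, 15), reads_per_gut = 200,
       error_rate = 0, chimera_rate = 0,
       predator_dna_fraction = 0.03, contaminant_fraction = 0.01,
       selection_weights = NULL)
}

# build scenario + simulate db, abundance, guts, reads
simulate_stage <- function(sim, seed) {
  sim <- utils::modifyList(default_simulate_block(), sim)
  db <- generate_reference_db(
    sim$n_prey_taxa, sim$haplotypes_per_taxon, sim$seq_length,
    sim$between_taxon_divergence, sim$within_taxon_divergence,
    seed = seed)
  prey <- unique(db$taxon_id[!db$is_predator & !db$is_contaminant])
  responses <- rep(c("increasing", "decreasing", "flat"),
                   length.out = length(prey))
  scenario <- community_scenario(
    sites = tibble(site_id = sprintf("S%02d", seq_len(sim$n_sites)),
                   intensity = seq(0, 2, length.out = sim$n_sites)),
    taxa = tibble(taxon_id = prey, response = responses,
                  baseline_abundance = sim$baseline_abundance,
                  response_slope = sim$response_slope),
    seasons = sim$seasons)
  abundance <- simulate_community(scenario, sim$noise_dispersion,
                                  seed = seed + 1L)
  predators <- unique(db$taxon_id[db$is_predator])
  # the second (stonefly) predator is lost from the most intensive sites
  absent <- tail(scenario$sites$site_id, sim$predator2_absent_sites)
  weights <- unlist(sim$selection_weights) %||% NULL

  guts <- list()
  gseed <- seed + 100L
  for (s in scenario$sites$site_id) {
    for (season in sim$seasons) {
      ab_row <- abundance |>
        filter(.data$site_id == s, .data$season == season)
      ab <- set_names(ab_row$count, ab_row$taxon_id)
      for (pred in predators) {
        if (pred == predators[2] && s %in% absent) next
        other <- setdiff(predators, pred)
        avail <- c(ab, set_names(sim$intraguild_abundance, other))
        gseed <- gseed + 1L
        guts[[length(guts) + 1L]] <-
          simulate_guts(avail, pred, sim$individuals_per_site,
                        selection_weights = weights,
                        site_id = s, season = season, seed = gseed) |>
          mutate(individual_id = paste(.data$individual_id, season, sep = "_"))
      }
    }
  }
  guts <- list_rbind(guts)
  class(guts) <- c("gut_truth", class(guts))
  reads <- simulate_reads(
    guts, db, mid_design = sim$mid_design, reads_per_gut = sim$reads_per_gut,
    error_rate = sim$error_rate, chimera_rate = sim$chimera_rate,
    predator_dna_fraction = sim$predator_dna_fraction,
    contaminant_fraction = sim$contaminant_fraction,
    seed = seed + 7L)
  list(db = db, scenario = scenario, abundance = abundance,
       guts = guts, sim = reads)
}

#' Diet incidence implied by simulated gut truth
#'
#' Converts a [simulate_guts()] truth table into the `diet_matrix` the
#' pipeline should recover under error-free sequencing.
#'
#' @param guts a `gut_truth` tibble.
#' @param taxa optional taxon set for the columns (default: union of
#'   consumed taxa).
#' @return a `diet_matrix`.
#' @export
truth_diet_matrix <- function(guts, taxa = NULL) {
  det <- guts |>
    select("individual_id", "consumed") |>
    tidyr::unnest_longer("consumed", values_to = "taxon") |>
    mutate(rank = "species")
  taxa <- taxa %||% sort(unique(det$taxon))
  build_diet_matrix(det, set_names(taxa, taxa),
                    guts[, DIET_ID_COLS])
}

#' Run the full diet-analysis pipeline from a configuration
#'
#' Executes simulate (optional) -> read processing -> diet matrix ->
#' null-model inference -> community summaries, writing tidy TSV/JSON
#' outputs and a manifest (package version, seeds, parameter values and
#' content digests per stage) under `config$out_dir`. Stage results are
#' cached on disk keyed by the digest of their inputs, so reruns that
#' only change downstream parameters resume from the cache; identical
#' configs reproduce identical outputs.
#'
#' @param config a validated configuration list (see
#'   [read_run_config()], [validate_run_config()]).
#' @return (invisibly) a list of class `dietlink_run` with all stage
#'   results and the manifest.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  manifest <- list(package = "dietlink",
                   version = as.character(utils::packageVersion("dietlink")),
                   seed = seed, config = config, stages = list())

  cached <- function(name, inputs, fun) {
    key <- rlang::hash(list(name, inputs))
    path <- file.path(cache_dir, paste0(name, "-", key, ".rds"))
    hit <- file.exists(path)
    res <- if (hit) readRDS(path) else {
      r <- fun()
      saveRDS(r, path)
      r
    }
    manifest$stages[[name]] <<- list(digest = key, cached = hit)
    res
  }

  # --- stage 1: obtain inputs -------------------------------------------
  if (!is.null(config$simulate)) {
    stage1 <- cached("simulate", list(config$simulate, seed),
                     function() simulate_stage(config$simulate, seed))
    db <- stage1$db
    abundance <- stage1$abundance
    reads <- stage1$sim$reads
    mid_map <- stage1$sim$mid_map
    metadata <- stage1$guts[, DIET_ID_COLS]
    write_barcode_fasta(db, file.path(out_dir, "barcodes.fasta"))
    readr::write_tsv(abundance, file.path(out_dir, "abundance.tsv"))
    readr::write_tsv(stage1$sim$truth, file.path(out_dir, "read_truth.tsv"))
    readr::write_tsv(mid_map, file.path(out_dir, "mid_map.tsv"))
    write_fasta(reads, file.path(out_dir, "reads.fasta"))
  } else {
    db <- read_barcode_fasta(config$inputs$db)
    abundance <- readr::read_tsv(config$inputs$abundance,
                                 show_col_types = FALSE)
    reads <- read_fasta(config$inputs$reads)
    mid_map <- readr::read_tsv(config$inputs$mids, show_col_types = FALSE)
    metadata <- readr::read_tsv(config$inputs$metadata %||%
                                  config$inputs$mids, show_col_types = FALSE)
    stage1 <- NULL
  }

  # --- stage 2: reads -> detections -------------------------------------
  sq <- config$seqproc
  grid <- seq(sq$grid_from, sq$grid_to, by = -abs(sq$grid_by))
  proc <- cached("seqproc", list(reads, mid_map, db, sq),
                 function() process_reads(
                   reads, mid_map, db, grid = grid,
                   min_copies = sq$min_copies, min_len = sq$min_len,
                   max_len = sq$max_len, max_mismatch = sq$max_mismatch))
  readr::write_tsv(proc$detections, file.path(out_dir, "detections.tsv"))
  readr::write_tsv(proc$diagnostics,
                   file.path(out_dir, "threshold_diagnostics.tsv"))
  write_fasta(tibble(read_id = proc$motus$representatives$motu_id,
                     sequence = proc$motus$representatives$sequence),
              file.path(out_dir, "motu_representatives.fasta"))

  # --- stage 3: diet matrix ---------------------------------------------
  rank_map <- distinct(db, .data$species_label, .data$taxon_id)
  rank_map <- set_names(rank_map$taxon_id, rank_map$species_label)
  species_det <- filter(proc$detections, .data$rank == "species")
  diet <- cached("dietcore", list(species_det, rank_map, metadata),
                 function() build_diet_matrix(species_det, rank_map, metadata))
  readr::write_tsv(diet, file.path(out_dir, "diet_matrix.tsv"))

  # --- stage 4: null-model inference ------------------------------------
  an <- config$analysis
  kick_taxa <- sort(unique(abundance$taxon_id))
  predators <- sort(unique(diet$predator_species))
  selection <- cached("nullmodels", list(diet, abundance, an, seed), function() {
    res <- list()
    for (pred in predators) {
      sub <- filter(diet, .data$predator_species == pred)
      keep <- intersect(diet_taxa(diet), kick_taxa)
      sub_k <- sub[, c(DIET_ID_COLS, keep)]
      class(sub_k) <- c("diet_matrix", class(sub_k))
      ab_long <- rename(abundance, taxon = "taxon_id")
      res[[pred]] <- prey_choice_null(sub_k, ab_long,
                                      n_iterations = an$n_iterations,
                                      conf = an$conf, seed = seed + 11L)
    }
    res
  })
  for (pred in names(selection)) {
    readr::write_tsv(selection[[pred]]$table,
                     file.path(out_dir, paste0("selection_", pred, ".tsv")))
  }

  overlap <- NULL
  breadth <- list()
  for (pred in predators) {
    sub <- filter(diet, .data$predator_species == pred)
    p <- utilization_vector(sub)
    n_avail <- sum(colSums(
      normalize_abundance(rename(abundance, taxon = "taxon_id"))) > 0)
    breadth[[pred]] <- tibble(
      predator_species = pred,
      n_individuals = nrow(sub),
      mean_prey = mean_prey_per_individual(sub),
      levins_BA = levins_breadth(p[p > 0] / sum(p[p > 0]), n_avail),
      selection_strength = selection[[pred]]$selection_strength)
  }
  breadth <- list_rbind(breadth)
  readr::write_tsv(breadth, file.path(out_dir, "niche_breadth.tsv"))
  if (length(predators) == 2) {
    overlap <- cached("overlap", list(diet, an, seed), function() {
      p1 <- utilization_vector(filter(diet,
                                      .data$predator_species == predators[1]))
      p2 <- utilization_vector(filter(diet,
                                      .data$predator_species == predators[2]))
      overlap_null_test(p1, p2, n_iterations = an$n_iterations,
                        seed = seed + 13L)
    })
    jsonlite::write_json(glance(overlap),
                         file.path(out_dir, "overlap_test.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # --- stage 5: community summaries -------------------------------------
  community <- cached("community", list(abundance, diet, seed), function() {
    site_tab <- abundance |>
      group_by(.data$site_id, .data$taxon_id) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "taxon_id", values_from = "count",
                         values_fill = 0)
    m <- as.matrix(site_tab[, -1]); rownames(m) <- site_tab$site_id
    d <- bray_curtis(m, transform = "fourth_root")
    ord <- nmds(d, k = 2, seed = seed + 17L)
    intensity <- abundance |>
      distinct(.data$site_id, .data$intensity) |>
      arrange(match(.data$site_id, rownames(m)))
    vf <- vector_fit(ord, intensity$intensity, seed = seed + 19L)
    acc <- lapply(set_names(predators), function(pred) {
      accumulation_curve(filter(diet, .data$predator_species == pred))
    })
    rar <- tibble(site_id = rownames(m),
                  richness = rowSums(m > 0),
                  rarefied = vapply(seq_len(nrow(m)), function(i)
                    rarefied_richness(m[i, ], min(rowSums(m))), numeric(1)))
    list(dissimilarity = d, ordination = ord, vector_fit = vf,
         accumulation = acc, rarefaction = rar)
  })
  readr::write_tsv(as_tibble(community$ordination$scores) |>
                     mutate(site_id = community$ordination$labels %||%
                              rownames(community$ordination$scores),
                            .before = 1),
                   file.path(out_dir, "nmds_scores.tsv"))
  readr::write_tsv(community$rarefaction, file.path(out_dir, "rarefaction.tsv"))
  for (pred in names(community$accumulation)) {
    readr::write_tsv(community$accumulation[[pred]]$curve,
                     file.path(out_dir, paste0("accumulation_", pred, ".tsv")))
  }

  manifest$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  res <- structure(list(
    config = config, manifest = manifest, db = db, abundance = abundance,
    truth = if (!is.null(stage1)) stage1$guts else NULL,
    seqproc = proc, diet = diet, selection = selection, breadth = breadth,
    overlap = overlap, community = community), class = "dietlink_run")
  invisible(res)
}
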