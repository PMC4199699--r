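#' Run the analysis pipeline from a single configuration
#'
#' Executes simulate -> mosaic / panel / diversity / traits stages in
#' dependency order from one declarative configuration (an R list or the
#' path of a YAML file) and writes every output with a manifest recording
#' inputs, parameters, the master seed and an MD5 checksum per file, so a
#' run can be replayed and verified. All randomness flows from the single
#' recorded seed.
#'
#' Configuration fields: `seed` (integer, required), `out_dir` (required),
#' `map` (path of a backbone map TSV; the bundled synthetic backbone is used
#' when omitted), `stages` (subset of `"simulate"`, `"mosaic"`, `"panel"`,
#' `"diversity"`, `"traits"`; default all), and optional stage parameter
#' blocks `simulate` (`n_offspring`, `n_backcross_lines`, `backcross_generations`,
#' `fragment_spacing_cM`, `error_rate`), `mosaic`, `panel` (`min_gain`,
#' `single_fragment_only`), `traits` (`baseline`, `penalty`, `n_spikelets`).
#'
#' @param config List or path to a YAML configuration file.
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop("config$seed is required")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  stages <- config$stages
  if (is.null(stages)) stages <- c("simulate", "mosaic", "panel", "diversity", "traits")
  known <- c("simulate", "mosaic", "panel", "diversity", "traits")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  if (!"simulate" %in% stages && length(setdiff(stages, "simulate")) > 0L) {
    stop("every analysis stage depends on 'simulate'")
  }
  if (!is.null(config$map) && !file.exists(config$map)) {
    stop("map file not found: ", config$map)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  files <- character(0)
  params <- list(seed = config$seed)

  map <- if (is.null(config$map)) example_backbone_map() else read_map(config$map)
  write_map(map, out("backbone_map.tsv"))
  files <- c(files, out("backbone_map.tsv"))

  set.seed(config$seed)
  sim <- config$simulate
  n_off <- sim$n_offspring %||% 200L
  n_bc <- sim$n_backcross_lines %||% 40L
  bc_gen <- sim$backcross_generations %||% 4L
  spacing <- sim$fragment_spacing_cM %||% 2
  err <- sim$error_rate %||% 0
  params$simulate <- list(n_offspring = n_off, n_backcross_lines = n_bc,
                          backcross_generations = bc_gen,
                          fragment_spacing_cM = spacing, error_rate = err)

  ## simulate: F3 mosaic population and a backcross panel, with truth
  frags <- make_dominant_markers(map, spacing = spacing)
  anchors <- data.frame(fragment = frags$name, group = frags$group,
                        position_cM = frags$position_cM, stringsAsFactors = FALSE)
  f1 <- simulate_pedigree(pedigree_spec(list(ped_cross(1L))), map)$population[[1]]
  founder <- combine_gametes(simulate_gamete(f1), simulate_gamete(f1), f1$bounds)
  offspring <- lapply(seq_len(n_off), function(i) {
    combine_gametes(simulate_gamete(founder), simulate_gamete(founder),
                    founder$bounds)
  })
  pop <- genotype_population(offspring, frags, error_rate = err)$fragments
  write_genotypes(pop, out("f3_fragments.tsv"))
  write_truth_painting(founder, out("founder_truth.tsv"))
  files <- c(files, out("f3_fragments.tsv"), out("founder_truth.tsv"))

  bc <- simulate_pedigree(pedigree_spec(list(
    ped_cross(1L), ped_backcross("Am", bc_gen, n_bc), ped_self(2L, n_bc))), map)
  ssr_markers <- make_codominant_markers(map)
  bc_geno <- genotype_population(bc$population, ssr_markers, error_rate = err,
                                 line_ids = sprintf("IL%03d", seq_len(n_bc)))$ssr
  write_genotypes(bc_geno, out("backcross_ssr.tsv"))
  files <- c(files, out("backcross_ssr.tsv"))

  manifest_results <- list()

  if ("mosaic" %in% stages) {
    rec <- reconstruct_from_population(pop, anchors, map)
    utils::write.table(rec$reconstruction$painting, out("founder_painting.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(
      crossover_events = as.list(rec$reconstruction$crossover_events),
      anchored_fraction = rec$reconstruction$anchored_fraction),
      out("crossovers.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, out("founder_painting.tsv"), out("crossovers.json"))
    manifest_results$mosaic <- list(
      n_events = sum(rec$reconstruction$crossover_events),
      anchored_fraction = rec$reconstruction$anchored_fraction)
  }

  if ("panel" %in% stages) {
    pp <- config$panel
    segs <- call_donor_segments(bc_geno, map)
    sel <- select_nonredundant(segs,
                               single_fragment_only = pp$single_fragment_only %||% TRUE,
                               min_gain = pp$min_gain %||% 1)
    rep_ <- coverage_report(attr(sel, "segments"), map)
    utils::write.table(segs, out("donor_segments.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(rep_), out("panel_coverage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(selected = as.character(sel),
                              totals = as.list(attr(rep_, "totals"))),
                         out("panel.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, out("donor_segments.tsv"), out("panel_coverage.tsv"),
               out("panel.json"))
    manifest_results$panel <- list(n_selected = length(sel),
                                   covered_cM = attr(rep_, "totals")$covered_cM)
  }

  if ("diversity" %in% stages) {
    d <- pairwise_distance(pop, metric = "jaccard")
    ord <- pcoa(d, k = 3L)
    utils::write.table(round(d, 6), out("distances.tsv"), sep = "\t", quote = FALSE)
    utils::write.table(round(ord$coordinates, 6), out("pcoa_coordinates.tsv"),
                       sep = "\t", quote = FALSE)
    files <- c(files, out("distances.tsv"), out("pcoa_coordinates.tsv"))
    manifest_results$diversity <- list(
      explained_fraction = ord$explained_fraction)
  }

  if ("traits" %in% stages) {
    tp <- config$traits
    fert <- do.call(rbind, lapply(seq_along(offspring), function(i) {
      cbind(line = sprintf("L%04d", i),
            simulate_fertility(offspring[[i]], tp$baseline %||% 0.8,
                               tp$penalty %||% 0.6, tp$n_spikelets %||% 50L))
    }))
    pct <- fertility_percent(fert$n_seeds, fert$n_spikelets,
                             fert$florets_per_spikelet)
    hs <- fertility_histogram(pct)
    utils::write.table(fert, out("fertility.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(list(mean = hs$mean, histogram = as.list(hs$histogram),
                              bimodal = hs$bimodal),
                         out("fertility_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, out("fertility.tsv"), out("fertility_summary.json"))
    manifest_results$traits <- list(mean_fertility_pct = hs$mean)
  }

  manifest <- list(
    seed = config$seed, stages = stages, parameters = params,
    results = manifest_results,
    outputs = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a ground-truth painting as TSV
#'
#' One row per homolog segment: `group`, `homolog`, `start`, `end`, `origin`.
#'
#' @param p A `chrom_painting`.
#' @param path Output path.
#' @export
write_truth_painting <- function(p, path) {
  rows <- list()
  for (g in names(p$groups)) {
    for (h in c("h1", "h2")) {
      s <- p$groups[[g]][[h]]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, homolog = h, start = s$start, end = s$end,
        origin = s$origin, stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
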