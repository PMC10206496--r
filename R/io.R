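#' Write / read the count-table dialect
#'
#' Tab-delimited text with columns `sample_id, replicate, compartment,
#' n_focal, n_partner, stage_focal, stage_partner` (extra columns are kept).
#'
#' @param counts count-table data.frame.
#' @param path file path.
#' @return `read_count_table` returns the validated data.frame;
#'   `write_count_table` returns `path` invisibly.
#' @export
write_count_table <- function(counts, path) {
  validate_count_table(counts)
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  counts <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_count_table(counts)
  counts
}

validate_count_table <- function(counts) {
  need <- c("sample_id", "replicate", "compartment", "n_focal", "n_partner",
            "stage_focal", "stage_partner")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0)
    stop("count table lacks columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(counts$compartment),
                 c("initial", "spores", "loners"))
  if (length(bad) > 0)
    stop("unknown compartment value(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Write / read the trajectory-table dialect
#'
#' Tab-delimited text with columns `cell_id, frame, time_s, x_um, y_um`, one
#' row per cell per frame, frames 0-based. `read_trajectory_table` tolerates
#' extra columns and tracker-exported column names via `mapping` (see
#' [as_trajectories]).
#'
#' @param tracks trajectory data.frame.
#' @param path file path.
#' @param mapping optional column mapping for foreign dialects.
#' @return the trajectory data.frame (read) or `path` invisibly (write).
#' @export
write_trajectory_table <- function(tracks, path) {
  tracks <- as_trajectories(tracks)
  utils::write.table(tracks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_table
#' @export
read_trajectory_table <- function(path, mapping = NULL) {
  as_trajectories(utils::read.delim(path, stringsAsFactors = FALSE),
                  mapping = mapping)
}

.config_schema <- list(
  seed = character(0),
  output_dir = character(0),
  generator = c("frequencies", "n_replicates", "n_events", "n_cells",
                "label_bias_a", "label_bias_b",
                "loner_prob_non_migrating", "loner_prob_migrating",
                "sporulation_weight_focal", "spore_fraction",
                "fraction_non_migrating_focal",
                "fraction_non_migrating_partner",
                "migrating_speed", "persistence_time",
                "non_migrating_diffusivity", "confinement_radius",
                "frame_interval", "duration", "n_tracked_cells"),
  bias = c("n_boot", "weighted_fit", "conf"),
  motility = c("lag_cutoff", "threshold", "max_lag", "overlapping"),
  evolution = c("f0", "n_generations", "tolerance"),
  adhesion = c("literal_supernatant", "stage_order")
)

#' Read and validate a pipeline run configuration
#'
#' Configurations are YAML or JSON (chosen by file extension). A mandatory
#' integer `seed` drives every random stream; unknown keys — at the top
#' level or inside a module block — are rejected so typos cannot silently
#' fall back to defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` config file.
#' @return the validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  config <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext)
  )
  validate_run_config(config)
  config
}

#' @rdname read_run_config
#' @param config a configuration list.
#' @export
validate_run_config <- function(config) {
  if (!is.list(config)) stop("config schema error: config must be a mapping")
  if (is.null(config$seed) || !is.numeric(config$seed))
    stop("config schema error: mandatory integer key 'seed' is missing")
  unknown <- setdiff(names(config), names(.config_schema))
  if (length(unknown) > 0)
    stop("config schema error: unknown key(s): ",
         paste(unknown, collapse = ", "))
  for (block in setdiff(names(config), c("seed", "output_dir"))) {
    bad <- setdiff(names(config[[block]]), .config_schema[[block]])
    if (length(bad) > 0)
      stop(sprintf("config schema error: unknown key(s) in '%s': %s",
                   block, paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

default_run_config <- function() {
  list(
    seed = 1L,
    generator = list(
      frequencies = seq(0.1, 0.9, by = 0.1), n_replicates = 3L,
      n_events = 10000L, n_cells = 10000L,
      label_bias_a = 0.12, label_bias_b = -0.1,
      loner_prob_non_migrating = 0.8, loner_prob_migrating = 0.1,
      sporulation_weight_focal = 1, spore_fraction = 0.8,
      fraction_non_migrating_focal = 0.5,
      fraction_non_migrating_partner = 0.15,
      migrating_speed = 0.1, persistence_time = 300,
      non_migrating_diffusivity = 0.01, confinement_radius = 0.5,
      frame_interval = 30, duration = 3600, n_tracked_cells = 600L
    ),
    bias = list(n_boot = 1000L, weighted_fit = FALSE, conf = 0.95),
    motility = list(lag_cutoff = 150, threshold = 0.5, overlapping = TRUE),
    evolution = list(f0 = 0.1, n_generations = 200L, tolerance = 1e-8)
  )
}

merge_config <- function(config, defaults = default_run_config()) {
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      for (k in names(defaults[[nm]]))
        if (is.null(config[[nm]][[k]]))
          config[[nm]][[k]] <- defaults[[nm]][[k]]
    }
  }
  config
}

#' Run the full synthetic chronochimera pipeline
#'
#' Deterministic end-to-end run driven by one seeded configuration:
#' \enumerate{
#'   \item simulate isogenic co-culture counts carrying the configured
#'     intrinsic label bias and fit the endpoint-constrained cubic label-bias
#'     profile;
#'   \item simulate a go-or-grow chimera frequency sweep, measure its
#'     compartments with the same label bias, compute raw and corrected
#'     spore and loner biases, and fit the corrected spore-bias profile;
#'   \item derive the between-generation frequency map, its fixed points and
#'     the behavior classification;
#'   \item simulate a tracked motility sample and run the MSD / slope /
#'     classification pipeline.
#' }
#' All tables are written as tab-delimited text, reports as JSON, the config
#' is echoed verbatim, and a run manifest (package version, seed, output
#' checksums) records provenance. Outputs are byte-identical for identical
#' `(config, seed)`.
#'
#' @param config configuration list (see [read_run_config]); defaults are
#'   filled in for absent keys.
#' @param output_dir output directory (created if needed); defaults to
#'   `config$output_dir`.
#' @return named list of output paths, invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  validate_run_config(config)
  config <- merge_config(config)
  output_dir <- output_dir %||% config$output_dir
  if (is.null(output_dir)) stop("an output directory is required")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  gen <- config$generator

  label_model <- bias_profile(gen$label_bias_a, gen$label_bias_b)
  validate_label_bias(label_model)

  # 1. isogenic co-cultures: zero true bias, measured with label bias
  cocult <- list(); k <- 0
  for (f in gen$frequencies) for (r in seq_len(gen$n_replicates)) {
    k <- k + 1
    sid <- sprintf("cocult_f%03d", round(100 * f))
    s0 <- child_seed(seed, sprintf("cocult_%d_init", k))
    s1 <- child_seed(seed, sprintf("cocult_%d_spore", k))
    cocult[[length(cocult) + 1]] <-
      sample_mix_counts(f, gen$n_events, label_bias = NULL, seed = s0,
                        sample_id = sid, replicate = r,
                        compartment = "initial",
                        stage_focal = "EE", stage_partner = "EE")
    cocult[[length(cocult) + 1]] <-
      sample_mix_counts(f, gen$n_events, label_bias = label_model, seed = s1,
                        sample_id = sid, replicate = r,
                        compartment = "spores",
                        stage_focal = "EE", stage_partner = "EE")
  }
  cocult <- do.call(rbind, cocult)
  cocult_bias <- compute_bias(cocult, outcome = "spores")
  wts <- if (isTRUE(config$bias$weighted_fit))
    rep(gen$n_events, nrow(cocult_bias)) else NULL
  label_fit <- fit_constrained_cubic(cocult_bias$f, cocult_bias$raw_bias,
                                     weights = wts,
                                     samples = unique(cocult_bias$sample_id))

  # 2. go-or-grow chimera sweep
  chim_counts <- list(); k <- 0
  for (f in gen$frequencies) for (r in seq_len(gen$n_replicates)) {
    k <- k + 1
    pars <- go_or_grow_params(
      f_init = f, n_cells = gen$n_cells,
      focal = motility_params(
        fraction_non_migrating = gen$fraction_non_migrating_focal,
        migrating_speed = gen$migrating_speed,
        persistence_time = gen$persistence_time,
        non_migrating_diffusivity = gen$non_migrating_diffusivity,
        confinement_radius = gen$confinement_radius,
        frame_interval = gen$frame_interval, duration = gen$duration),
      partner = motility_params(
        fraction_non_migrating = gen$fraction_non_migrating_partner,
        migrating_speed = gen$migrating_speed,
        persistence_time = gen$persistence_time,
        non_migrating_diffusivity = gen$non_migrating_diffusivity,
        confinement_radius = gen$confinement_radius,
        frame_interval = gen$frame_interval, duration = gen$duration),
      loner_prob_non_migrating = gen$loner_prob_non_migrating,
      loner_prob_migrating = gen$loner_prob_migrating,
      sporulation_weight_focal = gen$sporulation_weight_focal,
      spore_fraction = gen$spore_fraction,
      seed = child_seed(seed, sprintf("chimera_%d", k)))
    sim <- simulate_chimera(pars,
                            sample_id = sprintf("chimera_f%03d", round(100 * f)),
                            replicate = r,
                            stage_focal = "LE", stage_partner = "EE")
    chim_counts[[k]] <- measure_chimera(
      sim, gen$n_events, label_bias = label_model,
      seed = child_seed(seed, sprintf("chimera_measure_%d", k)))
  }
  chim_counts <- do.call(rbind, chim_counts)
  spore_tbl <- compute_bias(chim_counts, outcome = "spores",
                            label_bias = label_fit, ci = TRUE,
                            n_boot = config$bias$n_boot,
                            seed = child_seed(seed, "spore_ci"),
                            conf = config$bias$conf)
  loner_tbl <- compute_bias(chim_counts, outcome = "loners",
                            label_bias = label_fit, ci = TRUE,
                            n_boot = config$bias$n_boot,
                            seed = child_seed(seed, "loner_ci"),
                            conf = config$bias$conf)
  spore_fit <- fit_constrained_cubic(spore_tbl$f, spore_tbl$corrected_bias,
                                     samples = unique(spore_tbl$sample_id))

  # 3. evolutionary frequency map
  fmap <- frequency_map(spore_fit)
  fps <- find_fixed_points(fmap, tolerance = config$evolution$tolerance)
  trace <- iterate_map(fmap, config$evolution$f0,
                       config$evolution$n_generations)
  behavior <- classify_behavior(spore_fit, seq(0.05, 0.95, by = 0.05))

  # 4. motility sample
  traj_sim <- simulate_trajectories(
    motility_params(
      fraction_non_migrating = gen$fraction_non_migrating_focal,
      migrating_speed = gen$migrating_speed,
      persistence_time = gen$persistence_time,
      non_migrating_diffusivity = gen$non_migrating_diffusivity,
      confinement_radius = gen$confinement_radius,
      frame_interval = gen$frame_interval, duration = gen$duration),
    n_cells = gen$n_tracked_cells,
    seed = child_seed(seed, "trajectories"))
  mot <- analyze_trajectories(traj_sim$tracks,
                              lag_cutoff = config$motility$lag_cutoff,
                              threshold = config$motility$threshold,
                              max_lag = config$motility$max_lag,
                              overlapping = config$motility$overlapping)
  pop <- population_summary(mot$records)

  # write artifacts
  paths <- list(
    config = file.path(output_dir, "config.yaml"),
    cocult_counts = file.path(output_dir, "cocult_counts.tsv"),
    chimera_counts = file.path(output_dir, "chimera_counts.tsv"),
    bias_table = file.path(output_dir, "bias_table.tsv"),
    label_profile = file.path(output_dir, "label_bias_profile.json"),
    spore_profile = file.path(output_dir, "spore_bias_profile.json"),
    fixed_points = file.path(output_dir, "fixed_points.json"),
    iteration = file.path(output_dir, "iteration_trace.tsv"),
    behavior = file.path(output_dir, "behavior_classification.tsv"),
    trajectories = file.path(output_dir, "trajectories.tsv"),
    motility_records = file.path(output_dir, "motility_records.tsv"),
    motility_summary = file.path(output_dir, "motility_summary.json"),
    manifest = file.path(output_dir, "manifest.json")
  )
  yaml::write_yaml(config, paths$config)
  write_count_table(cocult, paths$cocult_counts)
  write_count_table(chim_counts, paths$chimera_counts)
  bias_table <- rbind(spore_tbl, loner_tbl)
  utils::write.table(bias_table, paths$bias_table, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  profile_json <- function(p) list(a = p$a, b = p$b, rss = p$rss,
                                   n_points = p$n_points)
  jsonlite::write_json(profile_json(label_fit), paths$label_profile,
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(profile_json(spore_fit), paths$spore_profile,
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(fps, paths$fixed_points, digits = NA, na = "null")
  utils::write.table(
    data.frame(generation = seq_along(trace) - 1, frequency = trace),
    paths$iteration, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(behavior, paths$behavior, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_trajectory_table(traj_sim$tracks, paths$trajectories)
  utils::write.table(mot$records, paths$motility_records, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n = pop$n, n_non_migrating = pop$n_non_migrating,
         fraction_non_migrating = pop$fraction_non_migrating,
         ci = unname(pop$ci), by_class = pop$by_class),
    paths$motility_summary, auto_unbox = TRUE, digits = NA)

  tables <- unlist(paths[setdiff(names(paths), "manifest")])
  sums <- tools::md5sum(tables)
  names(sums) <- basename(tables)
  manifest <- list(
    package = "chronochimera",
    version = as.character(utils::packageVersion("chronochimera")),
    seed = seed,
    outputs = as.list(sums)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE)
  invisible(paths)
}
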