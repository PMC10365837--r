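#' Run one pipeline stage from a configuration list
#'
#' The umbrella entry point tying the stages together; the bundled
#' `axonquant` Rscript (in `inst/exec/`) is a thin wrapper around this
#' function. Each stage reads its parameter block from `config`, runs the
#' corresponding package functions with a seeded RNG, writes its artifacts
#' into `out_dir` and drops a `provenance.json` carrying the config hash,
#' package version and seed, so identical config + seed reproduce identical
#' outputs.
#'
#' Stages and their config blocks:
#' * `simulate`: `transport` block (arguments of [transport_sim_config()]);
#'   writes `movie.tif` (+ sidecar), `truth_frames.csv`, `truth_vesicles.csv`.
#' * `transport`: `movie` (TIFF path), optional `path_csv` (x,y vertices,
#'   soma end first; defaults to a straight path along the stack) and
#'   `transport_analysis` parameters; writes `tracks.csv`, `summary.csv`,
#'   `kymograph.csv`.
#' * `exo`: `exo` block (arguments of [simulate_phluorin_movie()] plus
#'   `dF_threshold`); simulates test + reference fields, detects events and
#'   writes `events.csv`, `fields.csv` with the normalized activity.
#' * `em`: `em` block (arguments of [simulate_em_synapse()] or an
#'   `annotations` directory of per-synapse CSVs); writes `metrics.csv`.
#' * `coloc`: `coloc` block (arguments of [simulate_two_channel_puncta()]
#'   plus `vesicle_diameter`, `thresholds`); writes `coloc.csv`.
#' * `ppr`: `ppr` block (arguments of [simulate_epsc_pair()]); writes
#'   `ppr.csv`.
#' * `stats`: `table` (CSV path with `value,group[,factor2]`) and `design`;
#'   writes `report.json`.
#'
#' @param config Named list, or path to a JSON file containing one.
#' @param stage One of `simulate`, `transport`, `exo`, `em`, `coloc`, `ppr`,
#'   `stats`.
#' @param out_dir Output directory (created if needed).
#' @return Named list of written artifact paths, invisibly.
#' @export
run_pipeline <- function(config, stage, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stopf("invalid config: expected a named list or JSON path")
  stage <- match.arg(stage, c("simulate", "transport", "exo", "em",
                              "coloc", "ppr", "stats"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  set.seed(seed)
  artifacts <- list()
  add <- function(name, path) artifacts[[name]] <<- path

  if (stage == "simulate") {
    cfg <- do.call(transport_sim_config,
                   c(config$transport %||% list(), list(seed = seed)))
    sim <- simulate_axonal_movie(cfg)
    p <- file.path(out_dir, "movie.tif")
    attr(sim$movie, "pixel_size") <- cfg$pixel_size
    attr(sim$movie, "frame_interval") <- cfg$frame_interval
    write_stack(sim$movie, p); add("movie", p)
    add("truth_frames",
        write_results(sim$truth$frames, file.path(out_dir, "truth_frames.csv")))
    add("truth_vesicles",
        write_results(sim$truth$vesicles,
                      file.path(out_dir, "truth_vesicles.csv")))
  } else if (stage == "transport") {
    movie <- read_stack(config$movie)
    pars <- config$transport_analysis %||% list()
    path <- if (!is.null(config$path_csv)) {
      axon_path(readr::read_csv(config$path_csv, show_col_types = FALSE),
                width = pars$width %||% 5)
    } else {
      margin <- pars$x_margin_px %||% 4
      y0 <- (dim(movie)[1] + 1) / 2
      axon_path(data.frame(x = c(margin, dim(movie)[2] - margin),
                           y = c(y0, y0)), width = pars$width %||% 5)
    }
    tracks <- detect_and_link(
      movie, path,
      detect_sigma = pars$detect_sigma %||% 1.3,
      intensity_threshold = pars$intensity_threshold %||% 12,
      max_link_step = pars$max_link_step %||% 0.6)
    dt <- attr(movie, "frame_interval")
    summ <- summarize_axon(
      tracks,
      window_length_um = pars$window_length_um %||% 100,
      duration_s = dim(movie)[3] * dt, frame_interval = dt)
    kym <- extract_kymograph(movie, path)
    add("tracks", write_results(tracks, file.path(out_dir, "tracks.csv")))
    add("summary", write_results(summ, file.path(out_dir, "summary.csv")))
    kdf <- as.data.frame(unclass(kym))
    add("kymograph", write_results(kdf, file.path(out_dir, "kymograph.csv")))
  } else if (stage == "exo") {
    pars <- config$exo %||% list()
    thr <- pars$dF_threshold %||% 20
    sim_args <- pars[setdiff(names(pars), "dF_threshold")]
    n_ref <- pars$n_reference_fields %||% 3
    sim <- do.call(simulate_phluorin_movie,
                   c(sim_args[setdiff(names(sim_args), "n_reference_fields")],
                     list(seed = seed)))
    all_events <- list(); fields <- list()
    for (fld in seq_along(sim$fields)) {
      froi <- dplyr::filter(sim$rois, .data$field == fld)
      evs <- purrr::imap(sim$fields[[fld]], function(stack, acq) {
        ev <- detect_events(stack, froi, dF_threshold = thr)
        if (nrow(ev)) dplyr::mutate(ev, field = fld, acquisition = acq)
        else NULL
      })
      all_events[[fld]] <- dplyr::bind_rows(evs)
      fields[[fld]] <- tally_field(
        evs$pre %||% data.frame(),
        list(evs$post1 %||% data.frame(), evs$post2 %||% data.frame(),
             evs$post3 %||% data.frame()), field = fld)
    }
    fields <- dplyr::bind_rows(fields)
    # Reference group: additional fields simulated under the same settings.
    ref_sim <- do.call(simulate_phluorin_movie,
                       c(sim_args[setdiff(names(sim_args),
                                          c("n_reference_fields",
                                            "n_fields"))],
                         list(n_fields = n_ref, seed = seed + 1L)))
    refs <- purrr::map_dfr(seq_along(ref_sim$fields), function(fld) {
      froi <- dplyr::filter(ref_sim$rois, .data$field == fld)
      evs <- purrr::map(ref_sim$fields[[fld]], detect_events, rois = froi,
                        dF_threshold = thr)
      tally_field(evs$pre, evs[c("post1", "post2", "post3")], field = fld)
    })
    fields <- normalize_activity(fields, refs)
    add("events", write_results(dplyr::bind_rows(all_events),
                                file.path(out_dir, "events.csv")))
    add("fields", write_results(fields, file.path(out_dir, "fields.csv")))
  } else if (stage == "em") {
    pars <- config$em %||% list()
    if (!is.null(pars$annotations)) {
      geoms <- read_em_annotations(pars$annotations)
    } else {
      sim_args <- pars[setdiff(names(pars), c("band_width", "n_bands"))]
      geoms <- list(do.call(simulate_em_synapse,
                            c(sim_args, list(seed = seed)))$geometry)
    }
    metrics <- purrr::imap_dfr(geoms, function(g, i)
      dplyr::mutate(em_metrics(g, band_width = pars$band_width %||% 40,
                               n_bands = pars$n_bands %||% 3L),
                    synapse = i, .before = 1L))
    add("metrics", write_results(metrics, file.path(out_dir, "metrics.csv")))
  } else if (stage == "coloc") {
    pars <- config$coloc %||% list()
    dia <- pars$vesicle_diameter %||% 4
    thr <- pars$thresholds %||% c(15, 15)
    sim_args <- pars[setdiff(names(pars),
                             c("vesicle_diameter", "thresholds"))]
    sim <- do.call(simulate_two_channel_puncta,
                   c(sim_args, list(seed = seed)))
    res <- make_masks_and_count(
      list(dog_enhance(sim$ch1, dia), dog_enhance(sim$ch2, dia)), thr)
    out <- tibble::tibble(
      n_ch1 = res$counts$n_particles[1], n_ch2 = res$counts$n_particles[2],
      dual = res$dual_count, percent_coloc = res$percent_colocalization)
    add("coloc", write_results(out, file.path(out_dir, "coloc.csv")))
  } else if (stage == "ppr") {
    pars <- config$ppr %||% list()
    sweeps <- do.call(simulate_epsc_pair, c(pars, list(seed = seed)))
    res <- compute_ppr(sweeps)
    add("ppr", write_results(res, file.path(out_dir, "ppr.csv")))
  } else if (stage == "stats") {
    tab <- readr::read_csv(config$table, show_col_types = FALSE)
    rep <- stats_workflow(tab, design = config$design %||% "multi_group")
    p <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(design = rep$design, branch = rep$branch, test = rep$test,
           statistic = rep$statistic, p_value = rep$p_value,
           stars = rep$stars, posthoc = rep$posthoc,
           normality = rep$normality, outliers = rep$outlier_removal),
      p, auto_unbox = TRUE, digits = 9, force = TRUE)
    add("report", p)
  }

  prov <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(
    list(stage = stage, seed = seed, config_hash = config_hash(config),
         package_version = as.character(utils::packageVersion("axonquant")),
         timestamp = format(Sys.time(), tz = "UTC")),
    prov, auto_unbox = TRUE)
  artifacts$provenance <- prov
  invisible(artifacts)
}

#' Read per-synapse EM annotation CSVs
#'
#' Each synapse is described by three CSVs in `dir`:
#' `<id>_terminal.csv` and `<id>_active_zone.csv` (columns `x`, `y` in nm)
#' and `<id>_vesicles.csv` (centroid `x`, `y` in nm). A `units.json` sidecar
#' may declare `vesicle_radius_nm`.
#'
#' @param dir Directory of annotation CSVs.
#' @return Named list of `axq_synapse_geometry` objects.
#' @export
read_em_annotations <- function(dir) {
  terms <- list.files(dir, pattern = "_terminal\\.csv$", full.names = TRUE)
  if (length(terms) == 0L) stopf("no *_terminal.csv files in %s", dir)
  radius <- 20
  sidecar <- file.path(dir, "units.json")
  if (file.exists(sidecar))
    radius <- jsonlite::read_json(sidecar)$vesicle_radius_nm %||% radius
  out <- purrr::map(terms, function(tf) {
    id <- sub("_terminal\\.csv$", "", basename(tf))
    rd <- function(suffix)
      as.matrix(readr::read_csv(file.path(dir, paste0(id, suffix)),
                                show_col_types = FALSE))
    structure(list(
      terminal = rd("_terminal.csv"),
      active_zone = rd("_active_zone.csv"),
      vesicles = readr::read_csv(file.path(dir, paste0(id, "_vesicles.csv")),
                                 show_col_types = FALSE),
      vesicle_radius = radius), class = "axq_synapse_geometry")
  })
  names(out) <- sub("_terminal\\.csv$", "", basename(terms))
  out
}
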