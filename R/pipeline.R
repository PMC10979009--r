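#' Build and validate a pipeline configuration
#'
#' One nested list drives the whole pipeline; every stage parameter is
#' validated before any computation, and configurations round-trip
#' losslessly through YAML ([read_pipeline_config()] /
#' [write_pipeline_config()]).
#'
#' @param simulate `NULL`, or a list with `params` (arguments for
#'   [sim_params()]), `n_cells`, and optional `shape_mix`.
#' @param input `NULL`, or a list with `paths` (TIFF files), `channel_map`,
#'   and `n_z`.
#' @param pixel_size nm/px.
#' @param psf_sigma_nm PSF sigma in nm.
#' @param segment,foci,backbone,clusters,demograph,shapeclass Per-stage
#'   parameter lists; unspecified entries take the stage defaults.
#' @param seed Master seed.
#' @param output_dir Optional directory for CSV/JSON outputs.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, input = NULL,
                            pixel_size = 65.35, psf_sigma_nm = 120,
                            segment = list(), foci = list(), backbone = list(),
                            clusters = list(), demograph = list(),
                            shapeclass = list(),
                            seed = 1L, output_dir = NULL) {
  if (is.null(simulate) && is.null(input)) {
    stop("pipeline_config: provide either `simulate` or `input`", call. = FALSE)
  }
  if (!is.null(simulate)) {
    if (is.null(simulate$n_cells) || simulate$n_cells < 1) {
      stop("pipeline_config: `simulate$n_cells` must be >= 1", call. = FALSE)
    }
    # validate generator parameters up-front
    do.call(sim_params, c(simulate$params %||% list(),
                          list(pixel_size = pixel_size,
                               psf_sigma = psf_sigma_nm)))
  }
  defaults <- list(
    segment = list(channel = "cell", threshold_method = "otsu",
                   min_area_um2 = 1, roundness_min = 0.85),
    foci = list(min_prominence = 5, single_parb_prominence = 5),
    backbone = list(bin_um = 0.13, representative_length_um = 3.5,
                    n_angle_bins = 72L),
    clusters = list(stop_criterion = 3, max_spots = 40L,
                    link_radius_nm = NA_real_),
    demograph = list(channel = "DNA", order_by = "contrast"),
    shapeclass = list())
  merge1 <- function(stage, user) {
    d <- defaults[[stage]]
    unknown <- setdiff(names(user), names(d))
    if (stage != "shapeclass" && length(unknown)) {
      stop("pipeline_config: unknown ", stage, " parameter(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    utils::modifyList(d, user)
  }
  cfg <- list(simulate = simulate, input = input,
              pixel_size = pixel_size, psf_sigma_nm = psf_sigma_nm,
              segment = merge1("segment", segment),
              foci = merge1("foci", foci),
              backbone = merge1("backbone", backbone),
              clusters = merge1("clusters", clusters),
              demograph = merge1("demograph", demograph),
              shapeclass = shapeclass,
              seed = as.integer(seed), output_dir = output_dir)
  if (cfg$segment$roundness_min <= 0 || cfg$segment$roundness_min > 1) {
    stop("pipeline_config: `segment$roundness_min` must lie in (0, 1]",
         call. = FALSE)
  }
  if (cfg$backbone$bin_um <= 0 ||
      cfg$backbone$representative_length_um <= cfg$backbone$bin_um) {
    stop("pipeline_config: backbone bin/representative length invalid",
         call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the end-to-end analysis pipeline
#'
#' Simulates (or reads) fields of view, then runs segmentation, roundness
#' and single-ParB screening, backbone profiling, cluster decomposition,
#' demograph construction and shape classification. Per-cell failures are
#' logged as exclusions with a reason and do not abort the run; the
#' manifest records a monotone screening funnel (detected >= round-pass >=
#' single-ParB >= profiled). Fully reproducible given the config seed.
#'
#' @param config A [pipeline_config()].
#' @return A list: `manifest` (funnel counts + config echo), `cells`
#'   (per-cell acceptance table), `foci`, `profiles` (list), `clusters`,
#'   `shape_calls`, `demograph`, `condition_summary`, `exclusions`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must come from pipeline_config()", call. = FALSE)
  }
  px <- config$pixel_size
  psf <- config$psf_sigma_nm

  # --- acquire cells -------------------------------------------------------
  stacks <- list()
  if (!is.null(config$simulate)) {
    sim <- do.call(simulate_condition, list(
      params = do.call(sim_params, c(config$simulate$params %||% list(),
                                     list(pixel_size = px, psf_sigma = psf))),
      n_cells = config$simulate$n_cells,
      seed = config$seed,
      shape_mix = config$simulate$shape_mix))
    stacks <- lapply(sim$cells, function(cc) cc$stack)
  } else {
    paths <- config$input$paths
    stacks <- lapply(paths, read_stack,
                     channel_map = config$input$channel_map,
                     pixel_size = px, n_z = config$input$n_z %||% 1L)
  }

  exclusions <- list()
  cells_rows <- list()
  foci_rows <- list()
  cluster_rows <- list()
  profiles <- list()
  shape_rows <- list()
  n_detected <- 0L; n_round <- 0L; n_single <- 0L; n_profiled <- 0L
  cell_counter <- 0L

  for (fi in seq_along(stacks)) {
    stack <- stacks[[fi]]
    rois <- detect_cells(stack, channel = config$segment$channel,
                         threshold_method = config$segment$threshold_method,
                         min_area_um2 = config$segment$min_area_um2)
    n_detected <- n_detected + nrow(rois)
    if (nrow(rois) == 0) next
    rois_r <- screen_round(rois, config$segment$roundness_min)
    n_round <- n_round + nrow(rois_r)
    dropped <- setdiff(rois$cell_id, rois_r$cell_id)
    for (id in dropped) {
      exclusions <- c(exclusions, list(tibble::tibble(
        field = fi, roi = id, stage = "screen_round",
        reason = "roundness below threshold")))
    }
    if (nrow(rois_r) == 0) next
    parb_proj <- max_project(stack, "ParB")
    rois_r <- select_single_chromosome(
      rois_r, parb_proj, pixel_size = px, psf_sigma_nm = psf,
      min_prominence = config$foci$single_parb_prominence)
    rois_s <- dplyr::filter(rois_r, .data$single_parb_pass)
    n_single <- n_single + nrow(rois_s)
    for (id in setdiff(rois_r$cell_id, rois_s$cell_id)) {
      exclusions <- c(exclusions, list(tibble::tibble(
        field = fi, roi = id, stage = "select_single_chromosome",
        reason = "ParB focus count != 1")))
    }

    dna_proj <- max_project(stack, "DNA")
    for (ri in seq_len(nrow(rois_s))) {
      cell_counter <- cell_counter + 1L
      cid <- cell_counter
      mask <- rois_s$mask[[ri]]

      all_foci <- dplyr::bind_rows(lapply(
        setdiff(stack$channel_labels, "cell"), function(ch) {
          f <- detect_foci(max_project(stack, ch), mask, pixel_size = px,
                           psf_sigma_nm = psf,
                           min_prominence = config$foci$min_prominence)
          if (nrow(f)) dplyr::mutate(f, cell_id = cid, channel = ch,
                                     .before = 1) else NULL
        }))
      foci_rows <- c(foci_rows, list(all_foci))
      parb <- all_foci[all_foci$channel == "ParB", ][1, ]

      shape <- classify_shape(dna_proj, mask, pixel_size = px,
                              params = do.call(shape_params, config$shapeclass))
      shape_rows <- c(shape_rows, list(
        dplyr::mutate(shape, cell_id = cid, field = fi, .before = 1)))

      prof_ok <- FALSE
      tryCatch({
        bb <- fit_backbone(dna_proj, mask, parb, pixel_size = px,
                           n_angle_bins = config$backbone$n_angle_bins)
        prof <- align_and_flip(profile_along_backbone(
          stack, bb, bin_um = config$backbone$bin_um,
          representative_length_um = config$backbone$representative_length_um))
        profiles[[as.character(cid)]] <- prof
        prof_ok <- TRUE

        spots <- decompose_spots(dna_proj, mask, pixel_size = px,
                                 psf_sigma_nm = psf,
                                 stop_criterion = config$clusters$stop_criterion,
                                 max_spots = config$clusters$max_spots)
        cls <- group_clusters(spots,
                              link_radius_nm = config$clusters$link_radius_nm,
                              psf_sigma_nm = psf, parb_focus = parb)
        cls <- primary_cluster_stats(cls, parb, backbone = bb, pixel_size = px)
        if (nrow(cls)) {
          cluster_rows <- c(cluster_rows, list(
            dplyr::mutate(cls, cell_id = cid, .before = 1)))
        }
      }, shape_not_arclike = function(e) {
        exclusions <<- c(exclusions, list(tibble::tibble(
          field = fi, roi = rois_s$cell_id[ri], stage = "fit_backbone",
          reason = conditionMessage(e))))
      }, error = function(e) {
        exclusions <<- c(exclusions, list(tibble::tibble(
          field = fi, roi = rois_s$cell_id[ri], stage = "profile",
          reason = conditionMessage(e))))
      })
      if (prof_ok) n_profiled <- n_profiled + 1L
      cells_rows <- c(cells_rows, list(tibble::tibble(
        cell_id = cid, field = fi, roi = rois_s$cell_id[ri],
        roundness = rois_s$roundness[ri], profiled = prof_ok)))
    }
  }

  demo <- if (length(profiles) >= 1) {
    tryCatch(build_demograph(unname(profiles),
                             channel = config$demograph$channel,
                             order_by = config$demograph$order_by,
                             cell_ids = as.integer(names(profiles))),
             error = function(e) NULL)
  } else NULL

  shape_calls <- dplyr::bind_rows(shape_rows)
  summary <- if (nrow(shape_calls) > 0) {
    npicks <- min(100L, nrow(shape_calls))
    tryCatch(bootstrap_ratio(shape_calls, picks_per_series = npicks,
                             n_boot = 25L, seed = config$seed),
             error = function(e) NULL)
  } else NULL

  manifest <- list(
    n_fields = length(stacks),
    funnel = c(detected = n_detected, round_pass = n_round,
               single_parb = n_single, profiled = n_profiled),
    seed = config$seed,
    config = unclass(config))

  out <- list(manifest = manifest,
              cells = dplyr::bind_rows(cells_rows),
              foci = dplyr::bind_rows(foci_rows),
              clusters = dplyr::bind_rows(cluster_rows),
              profiles = profiles,
              shape_calls = shape_calls,
              demograph = demo,
              condition_summary = summary,
              exclusions = dplyr::bind_rows(exclusions))

  if (!is.null(config$output_dir)) write_pipeline_outputs(out, config$output_dir)
  out
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(result$foci, file.path(dir, "foci.csv"), row.names = FALSE)
  if (nrow(result$clusters)) {
    cl <- dplyr::select(result$clusters, -"spot_ids")
    utils::write.csv(cl, file.path(dir, "clusters.csv"), row.names = FALSE)
  }
  utils::write.csv(result$shape_calls, file.path(dir, "shape_calls.csv"),
                   row.names = FALSE)
  if (length(result$profiles)) {
    prof <- dplyr::bind_rows(lapply(names(result$profiles), function(id) {
      dplyr::mutate(tibble::as_tibble(result$profiles[[id]]),
                    cell_id = as.integer(id), .before = 1)
    }))
    utils::write.csv(prof, file.path(dir, "profiles.csv"), row.names = FALSE)
  }
  man <- result$manifest[c("n_fields", "funnel", "seed")]
  man$funnel <- as.list(man$funnel)
  jsonlite::write_json(man,
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(result$condition_summary)) {
    s <- result$condition_summary
    jsonlite::write_json(
      list(ratio_mean = s$ratio_mean, ratio_se = s$ratio_se,
           counts = s$counts, n_boot = s$n_boot,
           picks_per_series = s$picks_per_series),
      file.path(dir, "condition_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
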