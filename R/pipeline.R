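# Workflow orchestration: a portable analysis configuration (YAML), the
# staged pipeline (dendrite -> spines -> motion -> puncta -> export), and
# parameter transfer between experiments.

#' Analysis configuration
#'
#' Collects every tunable parameter of the pipeline plus the input
#' description. Configurations round-trip through YAML unchanged, so a
#' parameter set optimized on one image can be saved and transferred to the
#' other images of an experiment (see [transfer_parameters()]).
#'
#' @param input list: `stack` (TIFF path), `axis_order`, `n_time`,
#'   `n_channels`, `pixel_size`, `endpoints` (list of `(row, col)` pairs per
#'   dendrite: `list(list(start=, end=), ...)`), `spine_centers` (k x 2
#'   matrix, a CSV path with columns row, col, confidence, or NULL).
#' @param params named list overriding the analysis defaults.
#' @return an `analysis_config`.
#' @export
analysis_config <- function(input = list(), params = list()) {
  defaults <- list(
    filter_size = 5, threshold = "mean",
    gaussian_sigma = 2, width_multiplier = 1, smoothing_strength = 0.5,
    semi_minor = 2, max_semi_major = 30,
    drop_factor = 0.4, n_break = 3, max_extent = 30, min_confidence = 0.5,
    mode = "luminosity",
    gamma_dendrite = 30, gamma_synapse = 30,
    min_sigma = 1.5, max_sigma = 4, noise_floor = 0,
    reference_t = 1, channel = 1, upsample = 1,
    downsample_trigger = 512, tolerance = 2,
    baseline_thickness_um = 2
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0) stopf("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  p <- modifyList(defaults, params)
  if (!p$mode %in% c("luminosity", "area")) stopf("mode must be 'luminosity' or 'area'")
  if (p$gamma_dendrite < 0 || p$gamma_dendrite > 100 ||
      p$gamma_synapse < 0 || p$gamma_synapse > 100) stopf("gamma out of [0, 100]")
  structure(list(input = input, params = p), class = "analysis_config")
}

#' @rdname analysis_config
#' @param path YAML file.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$input$endpoints)) {
    y$input$endpoints <- lapply(y$input$endpoints, function(e) {
      list(start = as.numeric(e$start), end = as.numeric(e$end))
    })
  }
  if (!is.null(y$input$spine_centers) && is.list(y$input$spine_centers)) {
    y$input$spine_centers <- do.call(rbind, lapply(y$input$spine_centers, as.numeric))
  }
  analysis_config(input = y$input, params = y$params)
}

#' @rdname analysis_config
#' @param config an `analysis_config`.
#' @export
write_config <- function(config, path) {
  y <- list(input = config$input, params = config$params)
  if (!is.null(y$input$spine_centers) && is.matrix(y$input$spine_centers)) {
    y$input$spine_centers <- lapply(seq_len(nrow(y$input$spine_centers)),
                                    function(i) as.numeric(y$input$spine_centers[i, ]))
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Transfer analysis parameters to new inputs
#'
#' Returns a configuration with identical analysis parameters but new input
#' paths/endpoints, mirroring the optimize-on-one-image-then-apply-to-all
#' protocol. A warning is emitted when the pixel sizes of source and target
#' disagree, since physical-unit parameters then mean different things.
#'
#' @param source_config an `analysis_config`.
#' @param new_input replacement `input` list.
#' @return a new `analysis_config`.
#' @export
transfer_parameters <- function(source_config, new_input) {
  old_px <- source_config$input$pixel_size
  new_px <- new_input$pixel_size
  if (!is.null(old_px) && !is.null(new_px) && old_px != new_px) {
    warnf("pixel_size differs between source (%g) and target (%g): physical-unit parameters will rescale", old_px, new_px)
  }
  analysis_config(input = new_input, params = source_config$params)
}

pipeline_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%OS2"), stage, msg)
  writeLines(line, con)
}

#' Run the full analysis pipeline
#'
#' Executes the staged workflow on one stack: dendrite medial axis and
#' segmentation per endpoint pair, spine ROI generation / neck tracing /
#' classification, global and local motion correction (multi-timepoint
#' stacks), puncta detection in every ROI, and export of masks (PNG), ROIs
#' (ImageJ .roi), statistics (CSV + JSON), shift tables, and the resolved
#' configuration. A failed stage aborts with the stage name; a spine neck
#' that cannot be traced is logged, not fatal.
#'
#' @param config an `analysis_config`.
#' @param out_dir output directory.
#' @param stack optionally, an already-loaded [image_stack()] (otherwise
#'   `config$input$stack` is read from disk).
#' @return invisibly, a result bundle (dendrites, spines, puncta, shifts).
#' @export
run_pipeline <- function(config, out_dir, stack = NULL) {
  p <- config$params
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(logcon))
  stage <- "setup"
  res <- tryCatch({
    pipeline_log(logcon, stage, paste0(
      "parameters: ", paste(names(p), unlist(lapply(p, format)), sep = "=", collapse = " ")))
    if (is.null(stack)) {
      stage <- "load"
      stack <- read_stack(config$input$stack,
                          axis_order = config$input$axis_order %||% "xy",
                          n_time = config$input$n_time,
                          n_channels = config$input$n_channels,
                          pixel_size = config$input$pixel_size)
    }
    if (!is.null(config$input$pixel_size)) stack$pixel_size <- config$input$pixel_size
    shape <- frame_shape(stack)

    stage <- "motion-global"
    shifts <- NULL
    if (n_timepoints(stack) > 1) {
      mc <- correct_global(stack, reference_t = p$reference_t, channel = p$channel,
                           upsample = p$upsample)
      stack <- mc$stack
      shifts <- mc$shifts
      pipeline_log(logcon, stage, sprintf("corrected %d frames", nrow(shifts)))
    } else pipeline_log(logcon, stage, "single timepoint: skipped")

    stage <- "dendrite"
    eps <- config$input$endpoints
    if (is.null(eps) || length(eps) == 0) {
      stopf("no endpoints provided for dendrite 1: each dendrite needs a start/end pair")
    }
    frame <- get_frame(stack, p$reference_t, p$channel)
    bm <- binarize(frame, p$filter_size, p$threshold)
    cf <- build_cost_field(bm)
    edges <- detect_edges(frame, p$gaussian_sigma, p$filter_size, p$threshold)
    dendrites <- list()
    for (i in seq_along(eps)) {
      e <- eps[[i]]
      if (is.null(e$start) || is.null(e$end)) {
        stopf("dendrite %d: missing start or end point", i)
      }
      pth <- shortest_path(cf, e$start, e$end,
                           downsample_trigger = p$downsample_trigger,
                           tolerance = p$tolerance)
      prof <- compute_profile(pth, edges, semi_minor = p$semi_minor,
                              max_semi_major = p$max_semi_major,
                              width_multiplier = p$width_multiplier,
                              smoothing_strength = p$smoothing_strength)
      seg <- build_mask(pth, prof, shape, stack)
      dendrites[[i]] <- seg
      id <- sprintf("dendrite_%d", i)
      write_mask_png(seg$mask, file.path(out_dir, paste0(id, "_mask.png")))
      export_roi(segmented_line(pth$control_points,
                                widths = rowSums(prof$half_widths)[
                                  vapply(seq_len(nrow(pth$control_points)), function(j) {
                                    which.min((pth$full_rank[, 1] - pth$control_points[j, 1])^2 +
                                              (pth$full_rank[, 2] - pth$control_points[j, 2])^2)
                                  }, integer(1))] / 2),
                 file.path(out_dir, paste0(id, "_path.roi")))
      pipeline_log(logcon, stage, sprintf("%s: %d path px, mean width %.2f px",
                                          id, nrow(pth$full_rank),
                                          mean(rowSums(prof$half_widths))))
    }
    dend_stats <- do.call(rbind, lapply(seq_along(dendrites), function(i) {
      s <- dendrites[[i]]$stats
      n <- length(s$width_px)
      do.call(rbind, lapply(seq_len(n_timepoints(stack)), function(t) {
        do.call(rbind, lapply(seq_len(n_channels(stack)), function(ch) {
          data.frame(id = sprintf("dendrite_%d", i), t = t, c = ch,
                     point = seq_len(n),
                     axis_luminosity = s$axis_luminosity[t, ch, ],
                     width_px = s$width_px,
                     width_um = if (is.null(s$width_um)) NA_real_ else s$width_um)
        }))
      }))
    }))
    write_tables(dend_stats, file.path(out_dir, "dendrite_stats"))

    stage <- "spines"
    centers <- config$input$spine_centers
    if (is.character(centers)) {
      df <- read.csv(centers)
      centers <- as.matrix(df[, c("row", "col")])
      confs <- if ("confidence" %in% names(df)) df$confidence else rep(1, nrow(centers))
    } else confs <- NULL
    spines <- list()
    if (!is.null(centers) && nrow(centers) > 0) {
      cand <- lapply(seq_len(nrow(centers)), function(i) {
        spine_center(centers[i, 1], centers[i, 2],
                     confidence = if (is.null(confs)) 1 else confs[i])
      })
      cand <- filter_detections(cand, p$min_confidence)
      dend1 <- if (length(dendrites) > 0) dendrites[[1]] else NULL
      sp_par <- spine_params(p$drop_factor, p$n_break, p$max_extent)
      occupied <- matrix(FALSE, shape[1], shape[2])
      if (!is.null(dend1)) occupied <- occupied | dend1$mask
      for (i in seq_along(cand)) {
        rec <- make_spine_record(stack, cand[[i]], cand, dend1, mode = p$mode,
                                 channel = p$channel, params = sp_par)
        if (inherits(rec$neck, "neck_absent")) {
          pipeline_log(logcon, stage, sprintf("spine_%d: neck not traced (%s)",
                                              i, rec$neck$reason))
        }
        spines[[i]] <- rec
        occupied <- occupied | rasterize_polygon(rec$head_rois[[1]], shape)
      }
      for (i in seq_along(spines)) {
        spines[[i]]$background_roi <- tryCatch(
          place_background(spines[[i]]$head_rois[[1]], occupied, shape),
          error = function(e) NULL)
        if (n_timepoints(stack) > 1) {
          spines[[i]] <- correct_local(stack, spines[[i]],
                                       reference_t = p$reference_t,
                                       channel = p$channel, upsample = p$upsample)
        }
        export_roi(spines[[i]]$head_rois[[1]],
                   file.path(out_dir, sprintf("spine_%d_head.roi", i)))
      }
      spine_tab <- do.call(rbind, lapply(seq_along(spines), function(i) {
        spine_stats(spines[[i]], stack, id = sprintf("spine_%d", i))
      }))
      write_tables(spine_tab, file.path(out_dir, "spine_stats"))
      pipeline_log(logcon, stage, sprintf("%d spine records", length(spines)))
    } else pipeline_log(logcon, stage, "no spine centres supplied")

    stage <- "motion-local"
    if (!is.null(shifts)) {
      shift_tab <- data.frame(id = "global", t = seq_len(nrow(shifts)),
                              c = p$channel, drow = shifts[, 1], dcol = shifts[, 2])
      if (length(spines) > 0) {
        shift_tab <- rbind(shift_tab, do.call(rbind, lapply(seq_along(spines), function(i) {
          data.frame(id = sprintf("spine_%d", i), t = seq_len(n_timepoints(stack)),
                     c = p$channel, drow = spines[[i]]$local_shifts[, 1],
                     dcol = spines[[i]]$local_shifts[, 2])
        })))
      }
      write_tables(shift_tab, file.path(out_dir, "shifts"))
    }

    stage <- "puncta"
    policy <- threshold_policy(p$gamma_dendrite, p$gamma_synapse,
                               p$min_sigma, p$max_sigma,
                               noise_floor = p$noise_floor)
    puncta <- empty_puncta()
    for (t in seq_len(n_timepoints(stack))) {
      for (ch in seq_len(n_channels(stack))) {
        f <- get_frame(stack, t, ch)
        for (i in seq_along(dendrites)) {
          puncta <- rbind(puncta, detect_in_dendrite(
            f, dendrites[[i]]$path, dendrites[[i]]$profile, policy,
            parent_id = sprintf("dendrite_%d", i), t = t, c = ch))
        }
        for (i in seq_along(spines)) {
          roi <- head_roi_at(spines[[i]], t)
          puncta <- rbind(puncta, detect_in_polygon(
            f, roi, policy, gamma = p$gamma_synapse,
            parent_id = sprintf("spine_%d", i), t = t, c = ch))
        }
      }
    }
    puncta_tab <- cbind(id = if (nrow(puncta) > 0) puncta$parent_roi else character(0),
                        puncta)
    write_tables(puncta_tab, file.path(out_dir, "puncta"))
    pipeline_log(logcon, stage, sprintf("%d puncta", nrow(puncta)))

    stage <- "export"
    write_config(config, file.path(out_dir, "resolved_config.yaml"))
    pipeline_log(logcon, stage, "resolved config written")
    list(dendrites = dendrites, spines = spines, puncta = puncta,
         shifts = shifts, stack = stack)
  }, error = function(e) {
    pipeline_log(logcon, stage, paste("FAILED:", conditionMessage(e)))
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  invisible(res)
}
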