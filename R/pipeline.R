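#' Pipeline configuration
#'
#' Bundles and validates everything one analysis run needs.  Supply either a
#' group `preset` (a synthetic phantom emulating one treatment group) or an
#' existing `volume` (with optional ground `truth` for validation metrics).
#'
#' @param preset treatment group 1-4, or `NULL` when a volume is supplied.
#' @param volume a [volume3d()], or a file path readable by
#'   [read_volume_tiff()].
#' @param truth optional `phantom_truth` matching `volume`.
#' @param seed single integer; the only randomness in a run is phantom
#'   generation, which consumes this seed.
#' @param grid_shape phantom grid (presets only).
#' @param bin_width S(w) bin width in mm; `NULL` uses the preset's suggested
#'   width (0.01 mm otherwise).
#' @param smoothing_window moving-average window for anchor extraction, bins.
#' @param template `"A"`, `"B"` or `"auto"` (A when the peak width
#'   wM >= 0.05 mm, the broad/late-peak regime; B otherwise).
#' @param boundary boundary convention for [local_thickness()]; phantoms are
#'   crops of a larger wall, hence `"solid"`.
#' @param segmentation a [seg_config()].
#' @param n_section_points virtual-microscopy points per interface area.
#' @param out_dir optional output directory for the JSON report and CSV
#'   artifacts.  An existing non-empty directory is refused unless
#'   `overwrite = TRUE` (never silently overwritten).
#' @param overwrite allow writing into an existing non-empty `out_dir`.
#' @param write_volumes also write TIFF volume/mask/thickness artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(preset = NULL, volume = NULL, truth = NULL, seed = 1L,
                       grid_shape = c(128L, 128L, 128L), bin_width = NULL,
                       smoothing_window = 3L,
                       template = c("auto", "A", "B"),
                       boundary = c("solid", "background"),
                       segmentation = seg_config(),
                       n_section_points = 10L,
                       out_dir = NULL, overwrite = FALSE,
                       write_volumes = FALSE) {
  template <- match.arg(template)
  boundary <- match.arg(boundary)
  if (is.null(preset) == is.null(volume))
    stop("validation error: supply exactly one of `preset` or `volume`")
  if (!is.null(preset) && !preset %in% 1:4)
    stop("validation error: `preset` must be 1, 2, 3 or 4")
  if (is.character(volume)) {
    if (!file.exists(volume))
      stop("validation error: volume path does not exist: ", volume)
  } else if (!is.null(volume) && !inherits(volume, "volume3d")) {
    stop("validation error: `volume` must be a volume3d or a file path")
  }
  if (!is.null(bin_width) && bin_width <= 0)
    stop("validation error: bin_width must be > 0")
  if (!inherits(segmentation, "seg_config"))
    stop("validation error: `segmentation` must be a seg_config()")
  structure(list(preset = preset, volume = volume, truth = truth,
                 seed = as.integer(seed), grid_shape = as.integer(grid_shape),
                 bin_width = bin_width, smoothing_window = smoothing_window,
                 template = template, boundary = boundary,
                 segmentation = segmentation,
                 n_section_points = as.integer(n_section_points),
                 out_dir = out_dir, overwrite = overwrite,
                 write_volumes = write_volumes),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Chains simulate (for presets) -> segment -> local thickness -> S(w)
#' distribution -> anchors -> piecewise model fit -> closed-form integral,
#' plus virtual section widths.  Two volume statistics are reported:
#' `V` — the layer-cake volume `sum(area_i * w_i)`, the physical adhesive
#' volume used to rank treatment groups — and `V_model`, the closed-form
#' integral of the fitted per-bin S(w) model.  Identical config and seed
#' give identical reports.
#'
#' @param config a [run_config()].
#' @return A list of class `run_report` (also written as `report.json` to
#'   `out_dir` when configured).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(dir(out_dir, all.files = FALSE)) > 0 &&
        !config$overwrite)
      stop("output directory exists and is not empty: ", out_dir,
           " (set overwrite = TRUE to reuse it)")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }

  stage <- "simulate"
  report <- list(package = "adhesivect",
                 version = as.character(packageVersion("adhesivect")),
                 config = list(preset = config$preset, seed = config$seed,
                               grid_shape = config$grid_shape,
                               bin_width = config$bin_width,
                               smoothing_window = config$smoothing_window,
                               template = config$template,
                               boundary = config$boundary))
  res <- try({
    truth <- config$truth
    areas <- NULL
    bin_width <- config$bin_width
    if (!is.null(config$preset)) {
      spec <- group_preset(config$preset, grid_shape = config$grid_shape,
                           seed = config$seed)
      if (is.null(bin_width))
        bin_width <- attr(spec, "suggested_bin_width")
      ph <- generate_phantom(spec)
      vol <- ph$volume
      truth <- ph$truth
    } else {
      vol <- if (is.character(config$volume)) read_volume_tiff(config$volume)
             else config$volume
    }
    if (is.null(bin_width)) bin_width <- 0.01
    if (!is.null(truth)) areas <- truth$areas

    stage <- "segment"
    mask <- segment_adhesive(vol, config$segmentation)
    report$segmentation <- list(thresholds = attr(mask, "thresholds"),
                                n_voxels = sum(mask$mask))
    if (!is.null(truth))
      report$segmentation$dice_vs_truth <- dice_overlap(mask$mask, truth$mask)

    stage <- "thickness"
    tmap <- local_thickness(mask, boundary = config$boundary)
    tv <- tmap$values[!is.na(tmap$values)]
    report$thickness <- list(min = min(tv), median = median(tv), max = max(tv))

    stage <- "distribution"
    dist <- area_width_distribution(mask, tmap, bin_width = bin_width)
    anchors <- extract_anchors(dist, config$smoothing_window)
    report$distribution <- list(bin_width = bin_width,
                                total_area = sum(dist$areas),
                                n_bins_occupied = sum(dist$areas > 0))
    report$anchors <- unclass(anchors)

    stage <- "fit"
    template <- config$template
    if (template == "auto") template <- if (anchors$wM >= 0.05) "A" else "B"
    model <- fit_model(dist, template, anchors)
    report$model <- list(template = model$template, knots = model$knots,
                         pieces = model$pieces,
                         rss = model$fit_info$rss,
                         fallback = model$fit_info$fallback)

    stage <- "integrate"
    vstat <- integrate_model(model, group = config$preset)
    report$V_model <- vstat$V
    report$V <- thickness_weighted_volume(dist)
    if (!is.null(truth)) report$true_volume <- truth$true_volume

    stage <- "sections"
    plane <- dim(mask$mask)[2] %/% 2L
    widths <- virtual_section_widths(mask, 2L, plane,
                                     config$n_section_points, areas)
    report$section_widths <- list(
      plane_axis = 2L, plane_index = plane,
      by_area = lapply(split(widths$width_mm, widths$area), as.numeric))

    list(mask = mask, tmap = tmap, dist = dist, anchors = anchors,
         model = model, widths = widths, truth = truth)
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(attr(res, "condition"))))

  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    dist <- res$dist
    write.csv(data.frame(w_bin_left = dist$bin_edges[-length(dist$bin_edges)],
                         w_bin_right = dist$bin_edges[-1],
                         area_mm2 = dist$areas),
              file.path(out_dir, "distribution.csv"), row.names = FALSE)
    write.csv(res$widths, file.path(out_dir, "section_widths.csv"),
              row.names = FALSE)
    if (config$write_volumes) {
      if (!is.null(res$truth))
        write_volume_tiff(adhesive_mask(res$truth$mask, res$mask$voxel_size),
                          file.path(out_dir, "truth_mask.tif"))
      write_volume_tiff(res$mask, file.path(out_dir, "mask.tif"))
      tm <- res$tmap$values
      tm[is.na(tm)] <- 0
      write_volume_tiff(volume3d(tm, res$mask$voxel_size),
                        file.path(out_dir, "thickness_mm.tif"))
    }
  }
  attr(report, "objects") <- res
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>",
      if (!is.null(x$config$preset)) sprintf("group preset %d,", x$config$preset),
      sprintf("seed %d\n", x$config$seed))
  cat(sprintf("  thickness %.4g-%.4g mm, peak width %.4g mm\n",
              x$thickness$min, x$thickness$max, x$anchors$wM))
  cat(sprintf("  V (layer-cake) = %.5g mm^3; V_model (template %s) = %.5g mm^3\n",
              x$V, x$model$template, x$V_model))
  if (!is.null(x$true_volume))
    cat(sprintf("  true volume %.5g mm^3 (V recovers %.1f%%)\n",
                x$true_volume, 100 * x$V / x$true_volume))
  invisible(x)
}

#' Run all four group presets and rank their volumes
#'
#' @param seeds one or more replicate seeds; replicate i uses seed
#'   `seeds[i]` for every group.
#' @param groups subset of presets to run.
#' @param ... passed to [run_config()].
#' @return A list with `runs` (data.frame: group, seed, V, V_model, wM,
#'   dice), and `ordering` (per seed, TRUE when V strictly decreases along
#'   `groups`).
#' @export
run_group_comparison <- function(seeds = 1L, groups = 1:4, ...) {
  rows <- list()
  for (s in seeds) {
    for (g in groups) {
      rep <- run_pipeline(run_config(preset = g, seed = s, ...))
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, seed = s, V = rep$V, V_model = rep$V_model,
                   wM = rep$anchors$wM,
                   dice = rep$segmentation$dice_vs_truth)
    }
  }
  runs <- do.call(rbind, rows)
  ordering <- vapply(seeds, function(s) {
    v <- runs$V[runs$seed == s][order(runs$group[runs$seed == s])]
    all(diff(v) < 0)
  }, logical(1))
  names(ordering) <- seeds
  list(runs = runs, ordering = ordering)
}
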