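#' Pipeline configuration
#'
#' Binds the stitch -> optional interpolate -> optional evaluate stages
#' into one reproducible run description. Paths may be `NULL` to skip the
#' corresponding stage (interpolation is skipped when `anisotropy` is
#' `NULL`; evaluation when `gt` is `NULL`).
#'
#' @param z_masks Path to the z-mask volume (required).
#' @param yz_masks,xz_masks Optional paths to the orthogonal mask stacks;
#'   both or neither must be given.
#' @param gt Optional path to a ground-truth volume for evaluation.
#' @param out_dir Directory for all artifacts (created if missing).
#' @param stitch A [stitch_config()].
#' @param anisotropy Optional integer `N >= 2` enabling interpolation.
#' @param thresholds IoU thresholds for evaluation.
#' @param verbose Print per-stage progress.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(z_masks, yz_masks = NULL, xz_masks = NULL,
                            gt = NULL, out_dir,
                            stitch = stitch_config(), anisotropy = NULL,
                            thresholds = c(0.25, 0.5, 0.75),
                            verbose = FALSE) {
  if (is.null(yz_masks) != is.null(xz_masks)) {
    stop("give both orthogonal mask stacks or neither")
  }
  structure(list(z_masks = z_masks, yz_masks = yz_masks, xz_masks = xz_masks,
                 gt = gt, out_dir = out_dir, stitch = stitch,
                 anisotropy = anisotropy, thresholds = thresholds,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat key-value file
#'
#' Lines of the form `key = value` (`#` comments allowed) mirroring the
#' [pipeline_config()] arguments, e.g. `z_masks`, `yz_masks`, `xz_masks`,
#' `gt`, `out_dir`, `rejection_threshold`, `min_layers`, `anisotropy`,
#' `thresholds` (comma-separated).
#'
#' @param path Path to the config file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- lines[grepl("=", lines)]
  kv <- stats::setNames(
    trimws(sub("^[^=]*=", "", lines)),
    trimws(sub("=.*$", "", lines))
  )
  get_ <- function(k, default = NULL) if (k %in% names(kv)) kv[[k]] else default
  pipeline_config(
    z_masks = get_("z_masks"),
    yz_masks = get_("yz_masks"),
    xz_masks = get_("xz_masks"),
    gt = get_("gt"),
    out_dir = get_("out_dir", "."),
    stitch = stitch_config(
      rejection_threshold = as.numeric(get_("rejection_threshold", "0.5")),
      use_orthogonal_vote = as.logical(get_("use_orthogonal_vote", "TRUE")),
      min_layers_per_cell = as.integer(get_("min_layers", "2"))
    ),
    anisotropy = if (!is.null(get_("anisotropy"))) as.integer(get_("anisotropy")),
    thresholds = as.numeric(strsplit(get_("thresholds", "0.25,0.5,0.75"), ",")[[1]])
  )
}

#' Run the full reconstruction pipeline
#'
#' Validates all inputs, then executes stitch -> interpolate (optional)
#' -> evaluate (optional). Inputs on disk are never mutated; every
#' artifact goes to `out_dir`: `stitched.tif`, `interpolated.tif`,
#' `report.tsv`, the per-cell stitching decisions `stitch_log.tsv`, and a
#' machine-readable `manifest.json` recording the parameters. Identical
#' configurations produce identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the artifact paths, the stitched (and
#'   interpolated) volumes and the evaluation report, if computed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message(...)
  if (is.null(config$z_masks) || !file.exists(config$z_masks)) {
    stop("stitch stage: z_masks input missing")
  }
  for (p in c(config$yz_masks, config$xz_masks, config$gt)) {
    if (!file.exists(p)) stop("stitch stage: input not found: ", p)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  z_masks <- read_label_volume(config$z_masks)
  ortho <- NULL
  if (!is.null(config$yz_masks)) {
    ortho <- orthogonal_masks(read_label_volume(config$yz_masks),
                              read_label_volume(config$xz_masks))
    if (!all(dim(ortho$yz) == dim(z_masks))) {
      stop("stitch stage: orthogonal masks do not match the z-mask dimensions")
    }
  }
  say("stitching ", dim(z_masks)[1], " layers")
  stitched <- stitch_volume(z_masks, ortho, config$stitch)
  paths <- list(stitched = file.path(config$out_dir, "stitched.tif"))
  write_label_volume(stitched, paths$stitched)
  log <- attr(stitched, "stitch_log")
  if (!is.null(log)) {
    paths$stitch_log <- file.path(config$out_dir, "stitch_log.tsv")
    utils::write.table(log, paths$stitch_log, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  final <- stitched
  if (!is.null(config$anisotropy)) {
    say("interpolating at anisotropy ", config$anisotropy)
    final <- interpolate_volume(stitched,
                                interpolation_config(config$anisotropy))
    paths$interpolated <- file.path(config$out_dir, "interpolated.tif")
    write_label_volume(final, paths$interpolated)
  }
  report <- NULL
  if (!is.null(config$gt)) {
    gt <- read_label_volume(config$gt)
    if (!all(dim(gt) == dim(final))) {
      stop("evaluate stage: ground truth does not match the output dimensions")
    }
    report <- evaluate_segmentation(final, gt, config$thresholds)
    paths$report <- file.path(config$out_dir, "report.tsv")
    utils::write.table(report$per_threshold, paths$report, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    say("mAP = ", format(report$map, digits = 4))
  }
  manifest <- list(
    inputs = list(z_masks = config$z_masks, yz_masks = config$yz_masks,
                  xz_masks = config$xz_masks, gt = config$gt),
    stitch = unclass(config$stitch),
    anisotropy = config$anisotropy,
    thresholds = config$thresholds,
    artifacts = paths
  )
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(list(paths = paths, stitched = stitched, final = final,
                 report = report))
}
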