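#' Stitching configuration
#'
#' @param rejection_threshold Fraction in `[0, 1]`. Two OT-matched cell
#'   slices are stitched only when the proportion of rejecting orthogonal
#'   votes is *smaller* than this threshold. The default 0.5 requires a
#'   majority of votes to reject; 1 effectively accepts every match that
#'   is not unanimously rejected.
#' @param use_orthogonal_vote Whether to run the rejection vote at all.
#'   Without orthogonal masks the vote is skipped and every OT match is
#'   accepted.
#' @param min_layers_per_cell Cells whose support spans fewer distinct
#'   z-layers than this are removed in the final cleanup pass (default 2:
#'   drops cells confined to a single layer, the residue of repaired
#'   over-segmentation).
#' @return An object of class `stitch_config`.
#' @export
stitch_config <- function(rejection_threshold = 0.5,
                          use_orthogonal_vote = TRUE,
                          min_layers_per_cell = 2L) {
  if (rejection_threshold < 0 || rejection_threshold > 1) {
    stop("rejection_threshold must lie in [0, 1]")
  }
  if (min_layers_per_cell < 1L) stop("min_layers_per_cell must be positive")
  structure(list(rejection_threshold = rejection_threshold,
                 use_orthogonal_vote = isTRUE(use_orthogonal_vote),
                 min_layers_per_cell = as.integer(min_layers_per_cell)),
            class = "stitch_config")
}

#' Proportion of orthogonal votes rejecting a stitch
#'
#' Every pixel of the candidate cell slice in layer `z + 1` casts two
#' votes, one per orthogonal mask stack. The YZ vote of pixel `(r, c)`
#' rejects when the YZ-plane at X = `c` assigns different labels to
#' layers `z` and `z + 1` at row `r`; the XZ vote is symmetric. Two
#' background pixels carry equal labels (0 = 0) and therefore do not
#' reject. The returned fraction is `rejections / (2 * npixels)`.
#'
#' @param pixels Two-column matrix of 1-based `(row, col)` coordinates of
#'   the cell slice in layer `z + 1`.
#' @param z 1-based index of the upper layer of the pair.
#' @param ortho An [orthogonal_masks()] object covering layers `z` and
#'   `z + 1`.
#' @return A fraction in `[0, 1]`.
#' @export
rejection_fraction <- function(pixels, z, ortho) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) stop("empty pixel set")
  d <- dim(ortho$yz)
  if (z + 1L > d[1]) stop("layer z + 1 beyond volume depth")
  up <- cbind(z, pixels)
  lo <- cbind(z + 1L, pixels)
  rej <- sum(ortho$yz[lo] != ortho$yz[up]) + sum(ortho$xz[lo] != ortho$xz[up])
  rej / (2L * nrow(pixels))
}

#' Stitch one layer onto the previous relabeled layer
#'
#' Relabels the raw masks of layer `z + 1` consistently with the already
#' globally labeled layer `z`. For each foreground label `y` of the raw
#' layer, its least-cost tracer `x` under the optimal transport plan is
#' looked up; `y` inherits `x`'s global label unless no tracer exists, or
#' the rejection vote (when enabled and orthogonal masks are given)
#' reaches the threshold - in those cases `y` receives a fresh label from
#' the global counter. Each source label relabels at most one target
#' label, which is what repairs over-segmentation of layer `z`.
#'
#' @param relabeled_z Layer `z` carrying global labels.
#' @param raw_z1 Layer `z + 1` with its independent per-layer labels.
#' @param z 1-based index of layer `z` (for the orthogonal lookup).
#' @param ortho An [orthogonal_masks()] object, or `NULL` to skip voting.
#' @param config A [stitch_config()].
#' @param next_label First unused global label.
#' @return A list with `layer` (relabeled layer `z + 1`), `next_label`,
#'   and `log` (one row per target cell: decision and vote fraction).
#' @export
stitch_pair <- function(relabeled_z, raw_z1, z, ortho = NULL,
                        config = stitch_config(), next_label) {
  relabeled_z <- as_label_image(relabeled_z)
  raw_z1 <- as_label_image(raw_z1)
  if (!all(dim(relabeled_z) == dim(raw_z1))) stop("layers must share shape")
  cost <- jaccard_cost(relabeled_z, raw_z1)
  plan <- solve_transport(layer_distribution(relabeled_z),
                          layer_distribution(raw_z1), cost)
  tracing <- trace_cells(plan)
  out <- matrix(0L, nrow(raw_z1), ncol(raw_z1))
  targets <- sort(setdiff(unique(as.vector(raw_z1)), 0L))
  log <- vector("list", length(targets))
  for (k in seq_along(targets)) {
    y <- targets[k]
    x <- best_tracer(y, tracing, cost)
    frac <- NA_real_
    decision <- "matched"
    if (is.na(x)) {
      decision <- "new"
    } else if (!is.null(ortho) && config$use_orthogonal_vote) {
      pix <- which(raw_z1 == y, arr.ind = TRUE)
      frac <- rejection_fraction(pix, z, ortho)
      if (frac >= config$rejection_threshold) decision <- "rejected"
    }
    if (decision == "matched") {
      lab <- x
    } else {
      lab <- next_label
      next_label <- next_label + 1L
    }
    out[raw_z1 == y] <- lab
    log[[k]] <- data.frame(z_pair = z, target = y, source = x,
                           label = lab, decision = decision,
                           rejection = frac)
  }
  list(layer = out, next_label = next_label,
       log = if (length(log)) do.call(rbind, log) else NULL)
}

#' Stitch a z-stack of independently labeled masks into a 3D segmentation
#'
#' Runs the full top-to-bottom stitching pass: the first layer's labels
#' are mapped to fresh global labels (preserving its partition), each
#' subsequent layer is stitched onto its predecessor with
#' [stitch_pair()], and cells confined to fewer than
#' `min_layers_per_cell` layers are finally removed with
#' [remove_isolated_cells()] (skipped when the stack is shallower than
#' that minimum). Fresh labels are issued by a single counter starting
#' above the maximum raw label, so output labels never collide with input
#' ones.
#'
#' @param z_masks `(Z, Y, X)` volume of per-layer independent labels.
#' @param ortho Optional [orthogonal_masks()] of matching dimensions.
#' @param config A [stitch_config()].
#' @return The stitched `(Z, Y, X)` label volume, with the per-cell
#'   decision log in attribute `"stitch_log"`.
#' @export
stitch_volume <- function(z_masks, ortho = NULL, config = stitch_config()) {
  z_masks <- as_label_volume(z_masks)
  d <- dim(z_masks)
  if (d[1] < 1L) stop("need at least one layer")
  if (!is.null(ortho)) {
    if (!inherits(ortho, "orthogonal_masks")) stop("ortho must be orthogonal_masks()")
    if (!all(dim(ortho$yz) == d)) stop("orthogonal masks do not match volume dimensions")
  }
  out <- array(0L, dim = d)
  next_label <- max(z_masks) + 1L
  first <- matrix(z_masks[1, , ], d[2], d[3])
  for (l in sort(setdiff(unique(as.vector(first)), 0L))) {
    out[1, , ][first == l] <- next_label
    next_label <- next_label + 1L
  }
  logs <- list()
  if (d[1] > 1L) {
    for (z in seq_len(d[1] - 1L)) {
      res <- stitch_pair(matrix(out[z, , ], d[2], d[3]),
                         matrix(z_masks[z + 1L, , ], d[2], d[3]),
                         z, ortho, config, next_label)
      out[z + 1L, , ] <- res$layer
      next_label <- res$next_label
      logs[[z]] <- res$log
    }
  }
  min_layers <- min(config$min_layers_per_cell, d[1])
  out <- remove_isolated_cells(out, min_layers)
  attr(out, "stitch_log") <- if (length(logs)) do.call(rbind, logs) else NULL
  out
}

#' Remove cells confined to too few layers
#'
#' Sets to background every foreground label whose support spans fewer
#' than `min_layers` distinct z-indices. After stitching, such cells are
#' typically the unused remnants of over-segmented slices, which end up
#' isolated in single layers.
#'
#' @param volume A `(Z, Y, X)` label volume.
#' @param min_layers Minimum number of distinct layers a cell must span.
#' @return The cleaned volume.
#' @export
remove_isolated_cells <- function(volume, min_layers = 2L) {
  volume <- as_label_volume(volume)
  if (min_layers <= 1L) return(volume)
  d <- dim(volume)
  idx <- which(volume != 0L)
  if (!length(idx)) return(volume)
  labs <- volume[idx]
  zs <- (idx - 1L) %% d[1] + 1L     # z is the fastest-varying index
  span <- tapply(zs, labs, function(v) length(unique(v)))
  drop <- as.integer(names(span))[span < min_layers]
  if (length(drop)) volume[volume %in% drop] <- 0L
  volume
}
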