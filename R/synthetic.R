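# run expr under a private RNG stream, leaving the caller's stream intact
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Synthetic scene configuration
#'
#' Describes a deterministic 3D ground-truth cell volume: densely packed
#' convex cells (Voronoi regions of sampled seed points) or isolated
#' ellipsoids, inside a background margin.
#'
#' @param shape Integer vector `(Z, Y, X)`.
#' @param n_cells Number of cells to place.
#' @param seed Integer seed; all outputs are pure functions of
#'   `(config, seed)`.
#' @param min_seed_distance Minimum Euclidean distance between seed
#'   points, in voxels.
#' @param foreground_margin Width of the background shell at the volume
#'   faces, in voxels.
#' @param cell_model `"voronoi"` (space-filling convex cells, the packed
#'   epithelium-like case) or `"ellipsoid"` (solid balls of radius
#'   `cell_radius` around the seeds, clipped against neighbors).
#' @param cell_radius Radius for the ellipsoid model, in voxels.
#' @param seed_z_band Fraction of the z-extent (centered) within which
#'   Voronoi seeds are sampled. Confining seeds to a central slab makes
#'   the cells columnar - their cross-sections vary slowly from layer to
#'   layer, the locally cylindrical geometry that layer-wise stitching
#'   assumes. 1 spreads seeds over the full depth, which produces cells
#'   tapering to a point at their z-ends.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(shape, n_cells, seed = 1L, min_seed_distance = 6,
                         foreground_margin = 1L,
                         cell_model = c("voronoi", "ellipsoid"),
                         cell_radius = 8, seed_z_band = 0.5) {
  cell_model <- match.arg(cell_model)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L)) stop("shape must be (Z, Y, X), each >= 2")
  if (n_cells < 1L) stop("n_cells must be positive")
  if (seed_z_band <= 0 || seed_z_band > 1) stop("seed_z_band must lie in (0, 1]")
  structure(list(shape = shape, n_cells = as.integer(n_cells),
                 seed = as.integer(seed), min_seed_distance = min_seed_distance,
                 foreground_margin = as.integer(foreground_margin),
                 cell_model = cell_model, cell_radius = cell_radius,
                 seed_z_band = seed_z_band),
            class = "scene_config")
}

sample_seeds <- function(lo, hi, n, min_dist, max_tries = 1000L) {
  pts <- matrix(NA_real_, n, 3L)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- vapply(1:3, function(a) {
        if (hi[a] <= lo[a]) lo[a] else sample(seq(lo[a], hi[a]), 1L)
      }, 0)
      if (k == 1L ||
          min(sqrt(colSums((t(pts[seq_len(k - 1L), , drop = FALSE]) - cand)^2))) >=
            min_dist) {
        pts[k, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", n, " seeds at min distance ", min_dist,
           " after ", max_tries, " tries")
    }
  }
  pts
}

# squared distance field from one seed over the full grid
dist2_field <- function(shape, seed) {
  dz <- (seq_len(shape[1]) - seed[1])^2
  dy <- (seq_len(shape[2]) - seed[2])^2
  dx <- (seq_len(shape[3]) - seed[3])^2
  outer(outer(dz, dy, `+`), dx, `+`)
}

# is the voxel set of every label 6-connected and spanning >= 2 z-layers?
cells_well_formed <- function(vol) {
  d <- dim(vol)
  for (lab in setdiff(unique(as.vector(vol)), 0L)) {
    idx <- which(vol == lab)
    if (length(unique((idx - 1L) %% d[1])) < 2L) return(FALSE)
    member <- seen <- logical(prod(d))
    member[idx] <- TRUE
    seen[idx[1]] <- TRUE
    frontier <- idx[1]
    while (length(frontier)) {
      cz <- (frontier - 1L) %% d[1] + 1L
      cy <- ((frontier - 1L) %/% d[1]) %% d[2] + 1L
      cx <- (frontier - 1L) %/% (d[1] * d[2]) + 1L
      nb <- c(frontier[cz > 1L] - 1L, frontier[cz < d[1]] + 1L,
              frontier[cy > 1L] - d[1], frontier[cy < d[2]] + d[1],
              frontier[cx > 1L] - d[1] * d[2], frontier[cx < d[3]] + d[1] * d[2])
      frontier <- unique(nb[member[nb] & !seen[nb]])
      seen[frontier] <- TRUE
    }
    if (sum(seen) != length(idx)) return(FALSE)
  }
  TRUE
}

#' Generate a ground-truth 3D cell volume
#'
#' Samples seed points by uniform rejection (respecting
#' `min_seed_distance`, bounded retries), then labels voxels: under the
#' Voronoi model, every voxel inside the foreground region takes the
#' label of its nearest seed (ties to the lowest label); under the
#' ellipsoid model, voxels within `cell_radius` of a seed take the
#' nearest such seed's label. Scenes whose cells are not 6-connected or
#' span fewer than 2 z-layers are rejected and resampled (bounded
#' retries). Deterministic for a fixed config.
#'
#' @param config A [scene_config()].
#' @return A `(Z, Y, X)` label volume with labels `1..n_cells`, plus the
#'   seed coordinates in attribute `"seeds"`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  d <- config$shape
  with_seed(config$seed, {
    for (attempt in 1:20) {
      inset <- config$foreground_margin +
        if (config$cell_model == "ellipsoid") ceiling(config$cell_radius) else 0
      lo <- rep(1L + inset, 3L)
      hi <- d - inset
      if (any(hi < lo)) stop("shape too small for the requested margin/radius")
      zc <- (1 + d[1]) / 2
      zhalf <- config$seed_z_band * (d[1] - 1) / 2
      lo[1] <- max(lo[1], ceiling(zc - zhalf))
      hi[1] <- min(hi[1], floor(zc + zhalf))
      seeds <- sample_seeds(lo, hi, config$n_cells, config$min_seed_distance)
      best <- array(Inf, dim = d)
      lab <- array(0L, dim = d)
      for (k in seq_len(config$n_cells)) {
        d2 <- dist2_field(d, seeds[k, ])
        upd <- d2 < best
        best[upd] <- d2[upd]
        lab[upd] <- k
      }
      if (config$cell_model == "ellipsoid") {
        lab[best > config$cell_radius^2] <- 0L
      }
      m <- config$foreground_margin
      if (m > 0L) {
        lab[c(seq_len(m), d[1] - seq_len(m) + 1L), , ] <- 0L
        lab[, c(seq_len(m), d[2] - seq_len(m) + 1L), ] <- 0L
        lab[, , c(seq_len(m), d[3] - seq_len(m) + 1L)] <- 0L
      }
      if (length(setdiff(unique(as.vector(lab)), 0L)) == config$n_cells &&
          cells_well_formed(lab)) {
        attr(lab, "seeds") <- seeds
        return(lab)
      }
    }
    stop("failed to generate a well-formed scene in 20 attempts")
  })
}

#' Perturbation configuration for simulated 2D masks
#'
#' Emulates the failure modes of per-slice 2D segmentation:
#' over-segmentation (a cell slice split in two by a random chord through
#' its centroid), boundary noise (erosion/dilation within a radius) and
#' missed planes (blanked entirely).
#'
#' @param split_probability Per cell slice, probability of a chord split.
#' @param jitter_radius Maximum erosion/dilation radius in pixels
#'   (0 disables).
#' @param drop_probability Per plane, probability of blanking it.
#' @return An object of class `perturb_config`.
#' @export
perturb_config <- function(split_probability = 0, jitter_radius = 0,
                           drop_probability = 0) {
  stopifnot(split_probability >= 0, split_probability <= 1,
            drop_probability >= 0, drop_probability <= 1, jitter_radius >= 0)
  structure(list(split_probability = split_probability,
                 jitter_radius = jitter_radius,
                 drop_probability = drop_probability),
            class = "perturb_config")
}

# relabel one plane to 1..k and apply perturbations; draws RNG in a fixed
# order (drop, then per cell: split, jitter) for determinism
process_plane <- function(m, perturb) {
  labs <- sort(setdiff(unique(as.vector(m)), 0L))
  out <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_along(labs)) out[m == labs[k]] <- k
  if (is.null(perturb)) return(out)
  if (stats::runif(1) < perturb$drop_probability) {
    return(matrix(0L, nrow(m), ncol(m)))
  }
  nxt <- length(labs) + 1L
  for (k in seq_along(labs)) {
    pix <- which(out == k, arr.ind = TRUE)
    if (!nrow(pix)) next
    if (stats::runif(1) < perturb$split_probability) {
      theta <- stats::runif(1, 0, 2 * pi)
      ctr <- colMeans(pix)
      side <- (pix[, 2] - ctr[2]) * sin(theta) - (pix[, 1] - ctr[1]) * cos(theta) > 0
      if (any(side) && any(!side)) {
        out[pix[side, , drop = FALSE]] <- nxt
        nxt <- nxt + 1L
      }
    }
    if (perturb$jitter_radius >= 1) {
      r <- sample(seq_len(floor(perturb$jitter_radius)), 1L)
      grow <- stats::runif(1) < 0.5
      mask <- out == k
      brush <- EBImage::makeBrush(2L * r + 1L, "disc")
      if (grow) {
        big <- EBImage::dilate(mask * 1, brush) > 0
        out[big & out == 0L] <- k
      } else {
        small <- EBImage::erode(mask * 1, brush) > 0
        if (any(small)) out[mask & !small] <- 0L
      }
    }
  }
  out
}

#' Simulate per-plane 2D segmentation masks from a ground-truth volume
#'
#' Slices the volume along the chosen axis and relabels each plane
#' independently to `1..k` (the way a 2D segmenter labels each image on
#' its own), optionally applying [perturb_config()] corruptions. The
#' result keeps the `(Z, Y, X)` layout; labels are only meaningful within
#' one plane of the chosen axis.
#'
#' @param gt A `(Z, Y, X)` ground-truth label volume.
#' @param axis `"z"` (XY-planes), `"x"` (YZ-planes) or `"y"` (XZ-planes).
#' @param perturb A [perturb_config()] or `NULL` for clean masks.
#' @param seed Integer seed for the perturbation draws.
#' @return A `(Z, Y, X)` integer array of per-plane independent labels.
#' @export
slice_masks <- function(gt, axis = c("z", "x", "y"), perturb = NULL, seed = 1L) {
  axis <- match.arg(axis)
  gt <- as_label_volume(gt)
  d <- dim(gt)
  with_seed(seed, {
    if (axis == "z") {
      out <- array(0L, dim = d)
      for (z in seq_len(d[1])) {
        out[z, , ] <- process_plane(matrix(gt[z, , ], d[2], d[3]), perturb)
      }
      out
    } else {
      planes <- reslice(gt, axis)
      planes[] <- lapply(planes, process_plane, perturb = perturb)
      stack_planes(planes, axis)
    }
  })
}

#' Subsample a volume along Z
#'
#' Emulates increasing the anisotropy of an acquisition by keeping every
#' `factor`-th layer: layer `z` (0-based) survives when
#' `z mod factor == phase`. Keeping every other layer (`factor = 2`)
#' halves the Z-resolution.
#'
#' @param volume A `(Z, Y, X)` label volume with depth > `factor`.
#' @param factor Integer `N >= 2`.
#' @param phase 0-based offset of the first kept layer.
#' @return The subsampled volume, depth `ceiling((depth - phase) / factor)`.
#' @export
subsample_z <- function(volume, factor, phase = 0L) {
  volume <- as_label_volume(volume)
  factor <- as.integer(factor)
  if (factor < 2L) stop("factor must be an integer >= 2")
  if (dim(volume)[1] <= factor) stop("volume depth must exceed the factor")
  keep <- which((seq_len(dim(volume)[1]) - 1L) %% factor == phase)
  if (!length(keep)) stop("no layers kept: phase out of range")
  volume[keep, , , drop = FALSE]
}
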