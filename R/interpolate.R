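#' Interpolation configuration
#'
#' @param anisotropy Integer `N >= 2`: the z-spacing of the stitched
#'   volume expressed in XY pixel units. `N - 1` internal layers are
#'   reconstructed between every adjacent pair of original layers.
#' @param fill_method How interpolated contours become solid masks; the
#'   single supported method rasterizes the points, applies a 3x3 binary
#'   closing (rounding can perforate the contour) and fills the enclosed
#'   holes.
#' @param conflict_rule How voxels claimed by several cells' interpolants
#'   are resolved; `"first-wins"` keeps the claim of the lowest label.
#' @return An object of class `interpolation_config`.
#' @export
interpolation_config <- function(anisotropy,
                                 fill_method = "close-and-fill",
                                 conflict_rule = "first-wins") {
  anisotropy <- as.integer(anisotropy)
  if (is.na(anisotropy) || anisotropy < 2L) {
    stop("anisotropy must be an integer >= 2")
  }
  fill_method <- match.arg(fill_method)
  conflict_rule <- match.arg(conflict_rule)
  structure(list(anisotropy = anisotropy, fill_method = fill_method,
                 conflict_rule = conflict_rule),
            class = "interpolation_config")
}

#' Contour pixels of a cell slice
#'
#' Returns the 4-connectivity boundary of a label's support: every pixel
#' of the cell with at least one of its four edge-neighbors outside the
#' cell (image borders count as outside). Non-empty for any non-empty
#' slice.
#'
#' @param layer A 2D label matrix.
#' @param label A foreground label present in `layer`.
#' @return A two-column integer matrix of `(row, col)` coordinates.
#' @export
extract_boundary <- function(layer, label) {
  layer <- as_label_image(layer)
  mask <- layer == label
  if (!any(mask)) stop("label ", label, " absent from layer")
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  inner <- core &
    pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  which(mask & !inner, arr.ind = TRUE)
}

#' Optimal coupling between two cell contours
#'
#' Solves the exact 2-Wasserstein problem between the uniform
#' distributions on two boundary point sets, with squared Euclidean
#' distance as the cost. The support of the optimal plan is the partial
#' matching used for morphing: each positive-weight pair `(p, q, w)`
#' contributes an interpolated point.
#'
#' @param src,tgt Boundary point matrices from [extract_boundary()].
#' @return A list with `pairs` (matrix of source index, target index,
#'   weight), `src_points`, `tgt_points`, `coupling` and `objective`.
#' @export
boundary_coupling <- function(src, tgt) {
  src <- as.matrix(src); tgt <- as.matrix(tgt)
  ns <- nrow(src); nt <- nrow(tgt)
  if (ns == 0L || nt == 0L) stop("boundaries must be non-empty")
  C <- outer(src[, 1], tgt[, 1], `-`)^2 + outer(src[, 2], tgt[, 2], `-`)^2
  sol <- transport_simplex(rep(1 / ns, ns), rep(1 / nt, nt), C)
  pos <- which(sol$plan > 1e-12, arr.ind = TRUE)
  pairs <- cbind(src = pos[, 1], tgt = pos[, 2], weight = sol$plan[pos])
  list(pairs = pairs, src_points = src, tgt_points = tgt,
       coupling = sol$plan, objective = sol$objective)
}

# deterministic half-away-from-zero rounding (round() halves-to-even would
# make interpolated contours platform- and parity-dependent)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# rasterize contour points, close 1-pixel perforations, fill the interior
fill_contour <- function(points, shape) {
  m <- matrix(0L, shape[1], shape[2])
  m[points] <- 1L
  closed <- EBImage::closing(m, EBImage::makeBrush(3L, "box"))
  filled <- EBImage::fillHull(closed)
  matrix(as.integer(filled > 0), shape[1], shape[2])
}

#' Morph one cell slice into another across internal layers
#'
#' Reconstructs the `N - 1` equally spaced internal slices between a
#' matched source and target cell slice. The optimal boundary coupling is
#' computed once; the internal contour at fraction `alpha = k / N` is the
#' set of rounded weighted averages `(1 - alpha) p + alpha q` over all
#' coupled point pairs, which is then closed and filled into a solid
#' binary mask. When source and target supports are identical the
#' transported contour coincides with the original one at every fraction,
#' and the common support is returned unchanged.
#'
#' @param src_layer,tgt_layer Label matrices of equal shape.
#' @param src_label,tgt_label The matched cell's label in each layer.
#' @param config An [interpolation_config()].
#' @return A list of `N - 1` binary (0/1 integer) masks, ordered from the
#'   source side to the target side.
#' @export
interpolate_pair <- function(src_layer, src_label, tgt_layer, tgt_label,
                             config) {
  src_layer <- as_label_image(src_layer)
  tgt_layer <- as_label_image(tgt_layer)
  if (!all(dim(src_layer) == dim(tgt_layer))) stop("layers must share shape")
  src_mask <- src_layer == src_label
  tgt_mask <- tgt_layer == tgt_label
  if (!any(src_mask) || !any(tgt_mask)) stop("empty cell slice")
  n <- config$anisotropy
  if (identical(src_mask, tgt_mask)) {
    common <- matrix(as.integer(src_mask), nrow(src_mask), ncol(src_mask))
    return(rep(list(common), n - 1L))
  }
  bc <- boundary_coupling(extract_boundary(src_layer, src_label),
                          extract_boundary(tgt_layer, tgt_label))
  p <- bc$src_points[bc$pairs[, "src"], , drop = FALSE]
  q <- bc$tgt_points[bc$pairs[, "tgt"], , drop = FALSE]
  lapply(seq_len(n - 1L), function(k) {
    alpha <- k / n
    pts <- round_half_away((1 - alpha) * p + alpha * q)
    storage.mode(pts) <- "integer"
    fill_contour(pts, dim(src_layer))
  })
}

#' Reconstruct internal layers of an anisotropic stitched volume
#'
#' Expands a stitched volume of depth `D` to depth `(D - 1) * N + 1`:
#' original layers are placed unchanged at every `N`-th slot, and for
#' every cell present in both layers of an adjacent pair its `N - 1`
#' interpolated masks fill the slots in between (via
#' [interpolate_pair()]). Cells present on only one side of a pair
#' contribute no internal voxels - they stop at their last original
#' layer. Voxels claimed by several cells are resolved first-wins in
#' ascending label order.
#'
#' @param stitched A globally labeled `(Z, Y, X)` volume (output of
#'   [stitch_volume()]).
#' @param config An [interpolation_config()].
#' @return The interpolated `(Z, Y, X)` label volume.
#' @export
interpolate_volume <- function(stitched, config) {
  stitched <- as_label_volume(stitched)
  if (!inherits(config, "interpolation_config")) {
    stop("config must be an interpolation_config()")
  }
  d <- dim(stitched)
  n <- config$anisotropy
  out <- array(0L, dim = c((d[1] - 1L) * n + 1L, d[2], d[3]))
  for (z in seq_len(d[1])) out[(z - 1L) * n + 1L, , ] <- stitched[z, , ]
  if (d[1] < 2L) return(out)
  for (z in seq_len(d[1] - 1L)) {
    a <- matrix(stitched[z, , ], d[2], d[3])
    b <- matrix(stitched[z + 1L, , ], d[2], d[3])
    shared <- sort(intersect(setdiff(unique(as.vector(a)), 0L),
                             setdiff(unique(as.vector(b)), 0L)))
    for (lab in shared) {
      masks <- interpolate_pair(a, lab, b, lab, config)
      for (k in seq_len(n - 1L)) {
        zi <- (z - 1L) * n + 1L + k
        slice <- matrix(out[zi, , ], d[2], d[3])
        claim <- masks[[k]] == 1L & slice == 0L
        slice[claim] <- lab
        out[zi, , ] <- slice
      }
    }
  }
  out
}
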