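#' Validate and coerce a 3D label volume
#'
#' A label volume is a 3D integer array with axis order `(Z, Y, X)`: the
#' first index is the optical section (layer), the second the image row,
#' the third the image column. The value 0 is reserved for background;
#' any positive value is a cell instance label. Labels need not be
#' contiguous integers.
#'
#' @param x A 3D numeric array holding non-negative whole numbers.
#' @return The validated volume as a 3D integer array.
#' @export
as_label_volume <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("a label volume must be a 3D array with axes (Z, Y, X)")
  }
  if (anyNA(x)) stop("label volume contains NA values")
  if (is.double(x)) {
    if (any(x != floor(x))) stop("label volume pixels must be whole numbers")
    if (max(x) > .Machine$integer.max) stop("labels exceed the 32-bit integer range")
    storage.mode(x) <- "integer"
  }
  if (!is.integer(x)) stop("label volume pixels must be integer-typed")
  if (any(x < 0L)) stop("label pixels must be non-negative (0 = background)")
  x
}

#' Validate a 2D label image
#'
#' @param x A matrix of non-negative whole numbers; rows index Y, columns X.
#' @return The validated integer matrix.
#' @export
as_label_image <- function(x) {
  if (!is.matrix(x)) stop("a label image must be a matrix (rows = Y, cols = X)")
  v <- as_label_volume(array(x, dim = c(1L, dim(x))))
  matrix(v[1L, , ], nrow = nrow(x), ncol = ncol(x))
}

# smallest TIFF sample width out of {8, 16, 32} bits that holds `maxlab`.
# 32-bit TIFF pages written by the 'tiff' package round-trip exactly up to
# 2^24 - 1 (float mantissa width), which bounds the largest storable label.
choose_bits <- function(maxlab) {
  if (maxlab < 2^8) 8L else if (maxlab < 2^16) 16L else if (maxlab < 2^24) 32L
  else stop("maximum label ", maxlab, " exceeds the largest supported TIFF container (2^24 - 1)")
}

#' Read a label volume from disk
#'
#' Supported containers are multi-page TIFF (one page per Z-layer,
#' integer samples) and an RDS array archive holding a single 3D integer
#' array named `labels`. Values are preserved exactly; no rescaling is
#' applied.
#'
#' @param path Path to an existing file.
#' @param format `"tiff"` or `"rds"`. Defaults to a guess from the file
#'   extension.
#' @return A 3D integer array `(Z, Y, X)`.
#' @export
read_label_volume <- function(path, format = c("auto", "tiff", "rds")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "tiff"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "rds") {
    obj <- readRDS(path)
    if (!is.list(obj) || is.null(obj$labels)) {
      stop("array archive must contain a 3D array named 'labels'")
    }
    return(as_label_volume(obj$labels))
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    stop("ragged TIFF: pages do not share a common (height, width)")
  }
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, TRUE))) {
    stop("multi-channel TIFF pages are not label masks")
  }
  if (any(vapply(pages, function(p) any(p != floor(p)), TRUE))) {
    stop("non-integer pixel type: file is not a label mask")
  }
  vol <- array(0L, dim = c(length(pages), shapes[1, 1], shapes[2, 1]))
  for (z in seq_along(pages)) vol[z, , ] <- as.integer(pages[[z]])
  as_label_volume(vol)
}

#' Write a label volume to disk
#'
#' TIFF output picks the smallest of 8-, 16- or 32-bit samples that holds
#' the largest label, unless `bits` forces a width. Writing is lossless:
#' [read_label_volume()] inverts it bit for bit.
#'
#' @param volume A 3D label array `(Z, Y, X)`.
#' @param path Output file path.
#' @param format `"tiff"` or `"rds"` (guessed from the extension by default).
#' @param bits Optional forced TIFF sample width (8, 16 or 32); an error is
#'   raised if the largest label does not fit.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path, format = c("auto", "tiff", "rds"),
                               bits = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "tiff"
  }
  volume <- as_label_volume(volume)
  if (any(dim(volume) == 0L)) stop("cannot write an empty volume")
  if (format == "rds") {
    saveRDS(list(labels = volume), path)
    return(invisible(path))
  }
  maxlab <- max(volume)
  if (is.null(bits)) {
    bits <- choose_bits(maxlab)
  } else {
    bits <- as.integer(bits)
    if (!bits %in% c(8L, 16L, 32L)) stop("bits must be 8, 16 or 32")
    limit <- if (bits == 32L) 2^24 else 2^bits
    if (maxlab >= limit) {
      stop("maximum label ", maxlab, " overflows a ", bits, "-bit container")
    }
  }
  pages <- lapply(seq_len(dim(volume)[1]), function(z) {
    volume[z, , ] / (2^bits - 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' Reslice a volume into orthogonal planes
#'
#' Cuts a `(Z, Y, X)` volume into its cross-sections along X or Y:
#' `axis = "x"` yields one `(Z, Y)` plane per X index (YZ-planes),
#' `axis = "y"` one `(Z, X)` plane per Y index (XZ-planes). Pixel values
#' are copied, never relabeled.
#'
#' @param volume A 3D label array `(Z, Y, X)`.
#' @param axis `"x"` or `"y"`.
#' @return A list of label matrices with attribute `"axis"`.
#' @seealso [stack_planes()] for the inverse operation.
#' @export
reslice <- function(volume, axis = c("x", "y")) {
  axis <- match.arg(axis)
  volume <- as_label_volume(volume)
  if (any(dim(volume) == 0L)) stop("cannot reslice an empty volume")
  d <- dim(volume)
  planes <- if (axis == "x") {
    lapply(seq_len(d[3]), function(i) matrix(volume[, , i], d[1], d[2]))
  } else {
    lapply(seq_len(d[2]), function(i) matrix(volume[, i, ], d[1], d[3]))
  }
  attr(planes, "axis") <- axis
  planes
}

#' Reassemble orthogonal planes into a volume
#'
#' Inverse of [reslice()]: stacks YZ-planes (axis `"x"`) or XZ-planes
#' (axis `"y"`) back into a `(Z, Y, X)` volume.
#'
#' @param planes A list of matrices as returned by [reslice()].
#' @param axis `"x"` or `"y"`; defaults to the list's `"axis"` attribute.
#' @return A 3D integer array `(Z, Y, X)`.
#' @export
stack_planes <- function(planes, axis = attr(planes, "axis")) {
  axis <- match.arg(axis, c("x", "y"))
  d12 <- dim(planes[[1]])
  vol <- if (axis == "x") {
    array(0L, dim = c(d12[1], d12[2], length(planes)))
  } else {
    array(0L, dim = c(d12[1], length(planes), d12[2]))
  }
  for (i in seq_along(planes)) {
    if (!all(dim(planes[[i]]) == d12)) stop("ragged planes")
    if (axis == "x") vol[, , i] <- planes[[i]] else vol[, i, ] <- planes[[i]]
  }
  as_label_volume(vol)
}

#' Bundle orthogonal mask stacks for the rejection vote
#'
#' The stitching rejection vote consults 2D segmentations of the YZ- and
#' XZ-planes. Both stacks are stored as full `(Z, Y, X)` arrays aligned
#' with the z-mask volume; labels in `yz` carry meaning only within a
#' fixed X index, labels in `xz` only within a fixed Y index (each
#' orthogonal plane is segmented independently).
#'
#' @param yz `(Z, Y, X)` array of per-YZ-plane labels (independent per X).
#' @param xz `(Z, Y, X)` array of per-XZ-plane labels (independent per Y).
#' @return An object of class `orthogonal_masks`.
#' @export
orthogonal_masks <- function(yz, xz) {
  yz <- as_label_volume(yz)
  xz <- as_label_volume(xz)
  if (!all(dim(yz) == dim(xz))) stop("yz and xz stacks must share dimensions")
  structure(list(yz = yz, xz = xz), class = "orthogonal_masks")
}
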