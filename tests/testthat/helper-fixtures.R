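# shared fixtures and independent oracles, all built in code

# rasterized disc of radius r centered at (cy, cx) in an n x n image
disc_mask <- function(r, cy, cx, n) {
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  matrix(as.integer((yy - cy)^2 + (xx - cx)^2 <= r^2), n, n)
}

# do two volumes induce the same partition of voxels into cells?
partition_equal <- function(a, b) {
  if (!all((a == 0) == (b == 0))) return(FALSE)
  fg <- a != 0
  if (!any(fg)) return(TRUE)
  tab <- unique(cbind(a[fg], b[fg]))
  !any(duplicated(tab[, 1])) && !any(duplicated(tab[, 2]))
}

n_cells_of <- function(vol) length(setdiff(unique(as.vector(vol)), 0L))

iou_masks <- function(a, b) sum(a & b) / sum(a | b)

# independent sampler of feasible transport plans: northwest-corner fill
# after a random permutation of both marginals (a different construction
# from the simplex path, so it can serve as an optimality oracle)
random_feasible_plan <- function(a, b) {
  m <- length(a); n <- length(b)
  pi_ <- sample.int(m); pj <- sample.int(n)
  aa <- a[pi_]; bb <- b[pj]
  x <- matrix(0, m, n)
  i <- 1L; j <- 1L
  repeat {
    q <- min(aa[i], bb[j])
    x[i, j] <- q
    aa[i] <- aa[i] - q; bb[j] <- bb[j] - q
    if (i == m && j == n) break
    if (i == m) j <- j + 1L
    else if (j == n) i <- i + 1L
    else if (aa[i] <= bb[j]) i <- i + 1L
    else j <- j + 1L
  }
  out <- matrix(0, m, n)
  out[pi_, pj] <- x
  out
}

# random 2D label layer: k disjoint axis-aligned rectangles on an n x n grid
random_rect_layer <- function(n, k, jitter = 0L) {
  m <- matrix(0L, n, n)
  side <- floor(n / ceiling(sqrt(k)))
  pos <- expand.grid(seq(1, n - side + 1, by = side),
                     seq(1, n - side + 1, by = side))
  pos <- pos[seq_len(k), , drop = FALSE]
  for (i in seq_len(k)) {
    h <- sample(2:max(2, side - 2), 1)
    w <- sample(2:max(2, side - 2), 1)
    y0 <- pos[i, 1] + jitter * sample(-1:1, 1)
    x0 <- pos[i, 2] + jitter * sample(-1:1, 1)
    ys <- pmin(pmax(y0:(y0 + h - 1), 1), n)
    xs <- pmin(pmax(x0:(x0 + w - 1), 1), n)
    m[ys, xs] <- i
  }
  m
}

# exhaustive minimum-cost injective matching of targets to sources; an
# unmatched target prices at 1 (the cost of a disjoint pair)
brute_force_matching <- function(cost_fg) {
  ns <- nrow(cost_fg); nt <- ncol(cost_fg)
  best <- list(cost = Inf, assign = NULL)
  rec <- function(j, used, acc, assign) {
    if (acc >= best$cost) return()
    if (j > nt) {
      best <<- list(cost = acc, assign = assign)
      return()
    }
    rec(j + 1L, used, acc + 1, c(assign, NA_integer_))   # target j unmatched
    for (i in seq_len(ns)) {
      if (!(i %in% used)) {
        rec(j + 1L, c(used, i), acc + cost_fg[i, j], c(assign, i))
      }
    }
  }
  rec(1L, integer(0), 0, integer(0))
  best$assign
}

# exhaustive maximum one-to-one matching among candidate pairs (used to
# validate the greedy instance matcher); maximizes count, then total IoU
brute_force_instance_matching <- function(cand) {
  best <- list(n = -1L, iou = -Inf)
  rec <- function(i, used_p, used_g, n, siou) {
    if (n > best$n || (n == best$n && siou > best$iou)) {
      best <<- list(n = n, iou = siou)
    }
    if (i > nrow(cand)) return()
    rec(i + 1L, used_p, used_g, n, siou)
    if (!(cand$pred[i] %in% used_p) && !(cand$gt[i] %in% used_g)) {
      rec(i + 1L, c(used_p, cand$pred[i]), c(used_g, cand$gt[i]),
          n + 1L, siou + cand$iou[i])
    }
  }
  rec(1L, integer(0), integer(0), 0L, 0)
  best
}

# the columnar 20-cell scene used for the recovery experiments: seeds
# confined to a thin central z-slab so cell cross-sections vary slowly
# (the locally cylindrical geometry layer-wise stitching assumes)
recovery_scene_config <- function(seed = 7L) {
  scene_config(c(32L, 64L, 64L), 20L, seed = seed, min_seed_distance = 10,
               seed_z_band = 0.1)
}

# two cells stacked in z with identical XY footprints; the YZ masks
# distinguish them while the XZ masks do not, so exactly half of the
# orthogonal votes reject the stitch
stacked_cell_fixture <- function(h = 8L, w = 8L) {
  foot <- matrix(0L, h, w)
  foot[3:6, 3:6] <- 1L
  zm <- array(0L, c(4L, h, w))
  for (k in 1:4) zm[k, , ] <- foot
  yz <- array(0L, c(4L, h, w))
  for (k in 1:2) yz[k, , ][foot == 1L] <- 1L
  for (k in 3:4) yz[k, , ][foot == 1L] <- 2L
  xz <- array(0L, c(4L, h, w))
  for (k in 1:4) xz[k, , ] <- foot
  list(z_masks = zm, ortho = orthogonal_masks(yz, xz), footprint = foot)
}
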