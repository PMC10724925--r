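test_that("rejection fraction counts disagreeing orthogonal votes", {
  d <- c(2L, 5L, 4L)
  same <- array(3L, dim = d)
  ortho_same <- orthogonal_masks(same, same)
  pix <- cbind(rep(1:5, each = 2), rep(1:2, 5))   # 10 pixels
  expect_equal(rejection_fraction(pix, 1L, ortho_same), 0)

  flip <- array(rep(c(1L, 2L), times = prod(d[2:3]))[seq_len(prod(d))], dim = d)
  flip[1, , ] <- 1L; flip[2, , ] <- 2L
  expect_equal(rejection_fraction(pix, 1L, orthogonal_masks(flip, flip)), 1)

  # YZ disagrees at 4 of 10 pixels, XZ nowhere: 4 / 20
  yz <- array(3L, dim = d)
  for (k in 1:4) yz[2, pix[k, 1], pix[k, 2]] <- 99L
  expect_equal(rejection_fraction(pix, 1L, orthogonal_masks(yz, same)), 0.2)

  expect_error(rejection_fraction(pix[0, , drop = FALSE], 1L, ortho_same),
               "empty")
})

test_that("stitch_pair propagates, creates and arbitrates labels", {
  base <- matrix(0L, 8, 8)
  base[2:4, 2:4] <- 11L
  base[6:8, 6:8] <- 12L
  # identical raw layer with shuffled labels inherits the global labels
  raw <- matrix(0L, 8, 8)
  raw[2:4, 2:4] <- 2L
  raw[6:8, 6:8] <- 1L
  res <- stitch_pair(base, raw, 1L, NULL, stitch_config(), 100L)
  expect_equal(sort(unique(res$layer[res$layer > 0])), c(11L, 12L))
  expect_true(all((res$layer == 11L) == (raw == 2L)))
  expect_equal(res$next_label, 100L)

  # a disjoint new cell gets a fresh label
  raw2 <- matrix(0L, 8, 8)
  raw2[1, 8] <- 1L
  res2 <- stitch_pair(base, raw2, 1L, NULL, stitch_config(), 100L)
  expect_equal(unique(res2$layer[res2$layer > 0]), 100L)
  expect_equal(res2$next_label, 101L)

  # over-segmented source: two slices trace to one target, the lower-cost
  # (larger-overlap) one wins and the other relabels nothing
  over <- matrix(0L, 8, 8)
  over[2:5, 2:3] <- 21L           # 8 px
  over[2:5, 4:5] <- 22L           # 8 px
  target <- matrix(0L, 8, 8)
  target[2:5, 2:5] <- 1L          # covers both, more overlap with neither
  over[2:5, 4] <- 21L             # tilt: 21 now 12 px, 22 4 px
  res3 <- stitch_pair(over, target, 1L, NULL, stitch_config(), 100L)
  expect_equal(unique(res3$layer[res3$layer > 0]), 21L)
  expect_equal(res3$log$decision, "matched")
})

test_that("stitching a consistent cylinder yields one global cell", {
  zm <- array(0L, c(3, 6, 6))
  lab <- c(4L, 1L, 9L)            # per-layer labels shuffled
  for (k in 1:3) zm[k, 2:5, 2:5] <- lab[k]
  vol <- array(0L, c(3, 6, 6)); vol[, 2:5, 2:5] <- 1L
  ortho <- orthogonal_masks(vol, vol)
  st <- stitch_volume(zm, ortho, stitch_config())
  expect_equal(n_cells_of(st), 1L)
  expect_true(all((st != 0L) == (zm != 0L)))

  # a single-layer stack is returned as a relabeled copy
  one <- array(0L, c(1, 4, 4)); one[1, 1:2, 1:2] <- 5L
  st1 <- stitch_volume(one)
  expect_equal(n_cells_of(st1), 1L)
  expect_true(partition_equal(st1, one))
})

test_that("orthogonal voting splits stacked cells; threshold 1 merges them", {
  fx <- stacked_cell_fixture()
  st_vote <- stitch_volume(fx$z_masks, fx$ortho, stitch_config(rejection_threshold = 0.5))
  expect_equal(n_cells_of(st_vote), 2L)
  # the split happens exactly at the z2/z3 interface
  expect_equal(length(unique(st_vote[1:2, , ][st_vote[1:2, , ] > 0])), 1L)
  expect_equal(length(unique(st_vote[3:4, , ][st_vote[3:4, , ] > 0])), 1L)

  st_perm <- stitch_volume(fx$z_masks, fx$ortho, stitch_config(rejection_threshold = 1.0))
  expect_equal(n_cells_of(st_perm), 1L)
  st_off <- stitch_volume(fx$z_masks, fx$ortho,
                          stitch_config(use_orthogonal_vote = FALSE))
  expect_equal(n_cells_of(st_off), 1L)
})

test_that("raising the rejection threshold can only merge cells", {
  fx <- stacked_cell_fixture()
  counts <- vapply(c(0.25, 0.5, 0.75, 1.0), function(thr) {
    n_cells_of(stitch_volume(fx$z_masks, fx$ortho,
                             stitch_config(rejection_threshold = thr)))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 2L)
  expect_equal(counts[4], 1L)
})

test_that("isolated-layer cells are removed, spanning cells kept", {
  vol <- array(0L, c(4, 5, 5))
  vol[2, 2, 2] <- 7L                 # single-layer cell
  vol[3:4, 4, 4] <- 8L               # spans two layers
  out <- remove_isolated_cells(vol, 2L)
  expect_false(any(out == 7L))
  expect_equal(sum(out == 8L), 2L)
  expect_identical(remove_isolated_cells(vol, 1L), as_label_volume(vol))
})

test_that("stitched partition is invariant to per-layer label permutations", {
  cfg <- scene_config(c(12L, 24L, 24L), 6L, seed = 3, min_seed_distance = 8,
                      seed_z_band = 0.2)
  gt <- generate_scene(cfg)
  z <- slice_masks(gt, "z")
  ortho <- orthogonal_masks(slice_masks(gt, "x"), slice_masks(gt, "y"))
  st <- stitch_volume(z, ortho)
  set.seed(99)
  zp <- z
  for (k in seq_len(dim(z)[1])) {
    labs <- setdiff(unique(as.vector(z[k, , ])), 0L)
    if (!length(labs)) next
    perm <- sample(1000L + seq_along(labs))
    plane <- z[k, , ]
    for (i in seq_along(labs)) plane[z[k, , ] == labs[i]] <- perm[i]
    zp[k, , ] <- plane
  }
  stp <- stitch_volume(zp, ortho)
  expect_true(partition_equal(st, stp))
})
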