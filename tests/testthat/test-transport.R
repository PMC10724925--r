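test_that("layer distributions are label-mass proportions", {
  bg <- matrix(0L, 4, 4)
  d <- layer_distribution(bg)
  expect_equal(d$labels, 0L)
  expect_equal(d$masses, 1)

  one <- matrix(0L, 4, 4)
  one[1:2, 1:2] <- 5L
  d <- layer_distribution(one)
  expect_equal(d$labels, c(0L, 5L))
  expect_equal(d$masses, c(0.75, 0.25))

  two <- matrix(0L, 4, 4)
  two[1, 1:4] <- 3L            # 4 px
  two[3:4, 1:4] <- 9L          # 8 px
  d <- layer_distribution(two)
  expect_equal(d$labels, c(0L, 3L, 9L))
  expect_equal(d$masses, c(0.25, 0.25, 0.5))
  expect_equal(sum(d$masses), 1, tolerance = 1e-9)
})

test_that("Jaccard cost matches pixel enumeration", {
  a <- matrix(0L, 4, 4); a[2:3, 2:3] <- 1L
  cm <- jaccard_cost(a, a)
  expect_equal(cm$entries[2, 2], 0)      # identical supports, J = 1
  expect_equal(cm$entries[1, 1], 0)      # identical backgrounds too

  b <- matrix(0L, 4, 4); b[1, 1] <- 2L
  a2 <- matrix(0L, 4, 4); a2[4, 4] <- 1L
  cm <- jaccard_cost(a2, b)
  expect_equal(cm$entries[2, 2], 1)      # disjoint supports

  # 6-px cell vs 4-px cell overlapping in 2 px: J = 2/8, cost = 0.75
  x <- matrix(0L, 4, 4); x[1, 1:3] <- 1L; x[2, 1:3] <- 1L
  y <- matrix(0L, 4, 4); y[2:3, 2:3] <- 7L
  cm <- jaccard_cost(x, y)
  expect_equal(cm$entries[2, 2], 0.75)
  expect_true(all(cm$entries >= 0 & cm$entries <= 1))
  expect_error(jaccard_cost(x, matrix(0L, 3, 3)), "shape")
})

test_that("exact transport solutions are feasible and degenerate cases forced", {
  p1 <- list(labels = 0L, masses = 1)
  c1 <- list(entries = matrix(0.3, 1, 1), row_labels = 0L, col_labels = 0L)
  sol <- solve_transport(p1, p1, c1)
  expect_equal(sol$coupling, matrix(1, 1, 1))

  # zero-cost diagonal with equal masses puts everything on the diagonal;
  # the feasible set is the one-parameter family M = [[t, .5-t], [.5-t, t]]
  # whose cost 1 - 2t is minimized at t = 0.5
  p <- list(labels = c(0L, 1L), masses = c(0.5, 0.5))
  cm <- list(entries = matrix(c(0, 1, 1, 0), 2, 2),
             row_labels = c(0L, 1L), col_labels = c(0L, 1L))
  sol <- solve_transport(p, p, cm)
  expect_equal(sol$coupling, diag(0.5, 2), tolerance = 1e-12)
  expect_equal(sol$objective, 0)

  expect_error(
    solve_transport(list(labels = 0L, masses = 0.9), p1, c1),
    "sum to 1"
  )
})

test_that("plans reproduce their marginals and beat random feasible plans", {
  set.seed(101)
  for (k in 1:40) {
    layer_a <- random_rect_layer(16, sample(1:6, 1))
    layer_b <- random_rect_layer(16, sample(1:6, 1), jitter = 1L)
    pa <- layer_distribution(layer_a)
    pb <- layer_distribution(layer_b)
    cm <- jaccard_cost(layer_a, layer_b)
    sol <- solve_transport(pa, pb, cm)
    expect_lt(max(abs(rowSums(sol$coupling) - pa$masses)), 1e-8)
    expect_lt(max(abs(colSums(sol$coupling) - pb$masses)), 1e-8)
    expect_true(all(sol$coupling >= 0))
    for (s in 1:25) {
      rp <- random_feasible_plan(pa$masses, pb$masses)
      expect_lte(sol$objective, sum(cm$entries * rp) + 1e-9)
    }
  }
})

test_that("cell tracing follows the argmax with lowest-label ties", {
  # diagonal plan traces identically
  plan <- list(coupling = diag(c(0.4, 0.3, 0.3)),
               row_labels = c(0L, 2L, 5L), col_labels = c(0L, 2L, 5L))
  tr <- trace_cells(plan)
  expect_equal(tr$mapping, c("2" = 2L, "5" = 5L))
  expect_equal(tr$preimages[["2"]], 2L)

  # all-zero row traces to nothing; argmax on background traces to nothing
  cp <- matrix(0, 3, 3)
  cp[1, 1] <- 0.5
  cp[3, 1] <- 0.5          # label 5's mass all flows to background
  plan0 <- list(coupling = cp, row_labels = c(0L, 2L, 5L),
                col_labels = c(0L, 2L, 5L))
  tr0 <- trace_cells(plan0)
  expect_true(is.na(tr0$mapping[["2"]]))
  expect_true(is.na(tr0$mapping[["5"]]))

  # exact tie between two foreground columns resolves to the lower label
  cpt <- rbind(c(0, 0, 0), c(0, 0.25, 0.25), c(0, 0, 0.5))
  plant <- list(coupling = cpt, row_labels = c(0L, 1L, 2L),
                col_labels = c(0L, 3L, 8L))
  expect_equal(trace_cells(plant)$mapping[["1"]], 3L)
})

test_that("best_tracer takes the least-cost preimage or declares a new cell", {
  tracing <- list(mapping = c("1" = 7L, "2" = 7L),
                  preimages = list("7" = c(1L, 2L), "9" = integer(0)))
  cost <- list(entries = rbind(c(0, 1, 1), c(1, 0.3, 1), c(1, 0.6, 1)),
               row_labels = c(0L, 1L, 2L), col_labels = c(0L, 7L, 9L))
  expect_equal(best_tracer(7L, tracing, cost), 1L)
  expect_true(is.na(best_tracer(9L, tracing, cost)))
  one <- list(mapping = c("2" = 7L), preimages = list("7" = 2L))
  expect_equal(best_tracer(7L, one, cost), 2L)
})
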