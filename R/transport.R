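#' Label-mass distribution of a layer
#'
#' Turns a 2D label image into the discrete distribution used as an
#' optimal-transport marginal: each label's mass is its pixel count
#' divided by the total pixel count of the layer (background included).
#' Background (label 0) is always listed first, even when no background
#' pixel exists; foreground labels follow in ascending order.
#'
#' @param layer A 2D label matrix.
#' @return A list with `labels` (integer vector, 0 first) and `masses`
#'   (matching fractions summing to 1).
#' @export
layer_distribution <- function(layer) {
  layer <- as_label_image(layer)
  if (length(layer) == 0L) stop("layer is empty")
  labs <- sort(unique(as.vector(layer)))
  if (labs[1] != 0L) labs <- c(0L, labs)
  counts <- vapply(labs, function(l) sum(layer == l), 0L)
  list(labels = as.integer(labs), masses = counts / length(layer))
}

#' Jaccard stitching cost between two layers
#'
#' Builds the `(m+1) x (n+1)` cost matrix `C[x, y] = 1 - J(x, y)` where
#' `J` is the Jaccard index (intersection over union of pixel supports at
#' identical image coordinates) between label `x` of the first layer and
#' label `y` of the second. Background takes part as a full row and
#' column, computed by the same formula on the background supports. An
#' entry is 1 exactly when the two supports are disjoint (an empty
#' support is disjoint from everything).
#'
#' @param layer_z,layer_z1 Two label matrices of identical shape.
#' @return A list with `entries` (cost matrix), `row_labels` and
#'   `col_labels` (label vectors, background first).
#' @export
jaccard_cost <- function(layer_z, layer_z1) {
  layer_z <- as_label_image(layer_z)
  layer_z1 <- as_label_image(layer_z1)
  if (!all(dim(layer_z) == dim(layer_z1))) stop("layers must share shape")
  rl <- layer_distribution(layer_z)$labels
  cl <- layer_distribution(layer_z1)$labels
  fa <- factor(as.vector(layer_z), levels = rl)
  fb <- factor(as.vector(layer_z1), levels = cl)
  inter <- table(fa, fb)                     # |x ∩ y| at shared coordinates
  sa <- rowSums(inter)                       # |x|
  sb <- colSums(inter)                       # |y|
  uni <- outer(sa, sb, `+`) - inter
  J <- ifelse(uni > 0, as.matrix(inter) / uni, 0)
  entries <- 1 - J
  dimnames(entries) <- NULL
  list(entries = entries, row_labels = rl, col_labels = cl)
}

# Exact discrete optimal transport by the transportation simplex:
# northwest-corner start, MODI (dual) pricing, Bland-style first-negative
# entering rule and lexicographic leaving rule so degenerate (zero-mass)
# bases cannot cycle. Sizes here are tiny (labels per layer, boundary
# pixels per cell), so the dense O(mn) pivot is the right tool.
transport_simplex <- function(a, b, C, max_iter = 100000L) {
  m <- length(a); n <- length(b)
  stopifnot(nrow(C) == m, ncol(C) == n)
  if (abs(sum(a) - sum(b)) > 1e-8) stop("infeasible marginals: masses differ")
  x <- matrix(0, m, n)
  basis <- matrix(FALSE, m, n)
  i <- 1L; j <- 1L; ra <- a; rb <- b
  repeat {
    q <- min(ra[i], rb[j])
    x[i, j] <- q
    basis[i, j] <- TRUE
    ra[i] <- ra[i] - q; rb[j] <- rb[j] - q
    if (i == m && j == n) break
    # clamped advance: exactly one index moves per step, so the walk marks
    # m + n - 1 basic cells and cannot run off the grid on residual dust
    if (i == m) j <- j + 1L
    else if (j == n) i <- i + 1L
    else if (ra[i] <= rb[j]) i <- i + 1L
    else j <- j + 1L
  }
  for (iter in seq_len(max_iter)) {
    u <- rep(NA_real_, m); v <- rep(NA_real_, n)
    u[1] <- 0
    repeat {
      done <- TRUE
      for (ii in which(!is.na(u))) {
        js <- which(basis[ii, ] & is.na(v))
        if (length(js)) { v[js] <- C[ii, js] - u[ii]; done <- FALSE }
      }
      for (jj in which(!is.na(v))) {
        is_ <- which(basis[, jj] & is.na(u))
        if (length(is_)) { u[is_] <- C[is_, jj] - v[jj]; done <- FALSE }
      }
      if (done) break
    }
    if (anyNA(u) || anyNA(v)) stop("internal error: basis tree disconnected")
    red <- C - outer(u, rep(1, n)) - outer(rep(1, m), v)
    red[basis] <- 0
    ent <- which(red < -1e-10)
    if (!length(ent)) break
    ent <- ent[1L]
    ei <- (ent - 1L) %% m + 1L
    ej <- (ent - 1L) %/% m + 1L
    # unique alternating cycle closed by the entering cell: BFS through the
    # basis graph from row ei to column ej
    parent_row <- integer(m); parent_col <- integer(n)
    seen_r <- logical(m); seen_c <- logical(n)
    seen_r[ei] <- TRUE
    queue_r <- ei; queue_c <- integer(0)
    found <- FALSE
    while ((length(queue_r) || length(queue_c)) && !found) {
      if (length(queue_r)) {
        r <- queue_r[1L]; queue_r <- queue_r[-1L]
        for (cc in which(basis[r, ] & !seen_c)) {
          seen_c[cc] <- TRUE; parent_col[cc] <- r
          if (cc == ej) { found <- TRUE; break }
          queue_c <- c(queue_c, cc)
        }
      } else {
        cc <- queue_c[1L]; queue_c <- queue_c[-1L]
        for (r in which(basis[, cc] & !seen_r)) {
          seen_r[r] <- TRUE; parent_row[r] <- cc
          queue_r <- c(queue_r, r)
        }
      }
    }
    if (!found) stop("internal error: no pivot cycle")
    path <- list(); cc <- ej
    repeat {
      r <- parent_col[cc]
      path[[length(path) + 1L]] <- c(r, cc)
      if (r == ei) break
      cc <- parent_row[r]
      path[[length(path) + 1L]] <- c(r, cc)
    }
    minus <- path[seq(1L, length(path), by = 2L)]
    plus <- if (length(path) >= 2L) path[seq(2L, length(path), by = 2L)] else list()
    theta <- min(vapply(minus, function(p) x[p[1], p[2]], 0))
    leave <- NULL
    for (p in minus) if (x[p[1], p[2]] <= theta) { leave <- p; break }
    x[ei, ej] <- x[ei, ej] + theta
    for (p in minus) x[p[1], p[2]] <- x[p[1], p[2]] - theta
    for (p in plus) x[p[1], p[2]] <- x[p[1], p[2]] + theta
    basis[ei, ej] <- TRUE
    basis[leave[1], leave[2]] <- FALSE
    x[leave[1], leave[2]] <- 0
    if (iter == max_iter) stop("transportation simplex did not converge")
  }
  x[x < 0] <- 0
  list(plan = x, objective = sum(C * x))
}

#' Solve the stitching transport problem exactly
#'
#' Finds the coupling minimizing `<C, M>` over all non-negative matrices
#' with row sums `P` and column sums `P'` (the Kantorovich problem). The
#' solution is an exact linear-programming optimum, deterministic for
#' fixed input - no entropic regularization.
#'
#' @param p,p1 Marginals as returned by [layer_distribution()].
#' @param cost Cost structure as returned by [jaccard_cost()]; its label
#'   vectors must match the marginals.
#' @return A list with `coupling` (matrix), `objective`, `row_labels`,
#'   `col_labels`.
#' @export
solve_transport <- function(p, p1, cost) {
  if (abs(sum(p$masses) - 1) > 1e-6 || abs(sum(p1$masses) - 1) > 1e-6) {
    stop("marginals must each sum to 1")
  }
  if (abs(sum(p$masses) - sum(p1$masses)) > 1e-8) {
    stop("infeasible marginals: total masses differ")
  }
  if (!identical(p$labels, cost$row_labels) ||
      !identical(p1$labels, cost$col_labels)) {
    stop("cost matrix labels do not match the marginals")
  }
  sol <- transport_simplex(p$masses, p1$masses, cost$entries)
  list(coupling = sol$plan, objective = sol$objective,
       row_labels = cost$row_labels, col_labels = cost$col_labels)
}

#' Cell tracing function of a transport plan
#'
#' Each foreground source label `x` traces to the target label receiving
#' the largest share of its mass, `argmax_y M[x, y]`. When that argmax is
#' the background column, or the row carries no mass, `x` traces to
#' nothing. Ties go to the lowest label (columns are ordered background
#' first, then ascending). The inverse image (`preimages`) lists, per
#' foreground target label, the source labels tracing to it.
#'
#' @param plan A solved plan from [solve_transport()].
#' @return A list with `mapping` (named integer vector over foreground
#'   source labels; `NA` = traces to nothing) and `preimages` (named list
#'   over foreground target labels).
#' @export
trace_cells <- function(plan) {
  src <- plan$row_labels
  tgt <- plan$col_labels
  fg_src <- src[src != 0L]
  mapping <- stats::setNames(rep(NA_integer_, length(fg_src)), fg_src)
  for (x in fg_src) {
    row <- plan$coupling[match(x, src), ]
    if (all(row <= 0)) next
    y <- tgt[which.max(row)]           # first max = lowest label on ties
    if (y != 0L) mapping[as.character(x)] <- y
  }
  fg_tgt <- tgt[tgt != 0L]
  preimages <- stats::setNames(
    lapply(fg_tgt, function(y) {
      as.integer(names(mapping))[!is.na(mapping) & mapping == y]
    }),
    fg_tgt
  )
  list(mapping = mapping, preimages = preimages)
}

#' Least-cost tracer of a target cell
#'
#' Among the source cells tracing to target label `y`, returns the one
#' with the smallest stitching cost `C[x, y]` (ties to the lowest label).
#' Returns `NA` when no source traces to `y` - in the stitching algorithm
#' that target is then declared a new cell.
#'
#' @param y A foreground target label.
#' @param tracing Result of [trace_cells()].
#' @param cost The [jaccard_cost()] structure used to solve the plan.
#' @return The source label, or `NA_integer_`.
#' @export
best_tracer <- function(y, tracing, cost) {
  xs <- tracing$preimages[[as.character(y)]]
  if (is.null(xs) || length(xs) == 0L) return(NA_integer_)
  xs <- sort(xs)
  cs <- cost$entries[match(xs, cost$row_labels), match(y, cost$col_labels)]
  xs[which.min(cs)]
}
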