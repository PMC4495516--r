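# small in-code fixtures shared across tests

# a continuous-layer stack from a function of cell-center coordinates
fun_stack <- function(nr = 10, nc = 10, cellsize = 1,
                      f = function(x, y) x + y, name = "v", ...) {
  m <- outer(seq_len(nr), seq_len(nc), function(r, c) {
    x <- (c - 0.5) * cellsize
    y <- (nr - r + 0.5) * cellsize
    f(x, y) + 0 * x
  })
  raster_stack(stats::setNames(list(m), name), cellsize = cellsize, ...)
}

# occurrence set placed at the centers of given (row, col) cells
occ_at_cells <- function(stack, rows, cols, species = "sp") {
  ctr <- cell_center(stack, rows, cols)
  occurrence_set(species, ctr$x, ctr$y, stack)
}

# hand-built feature expansion over an explicit background feature matrix
manual_features <- function(F, classes = rep("linear", ncol(F))) {
  nr <- 1L; nc <- nrow(F)  # background = one grid row, one cell per column
  stack <- raster_stack(list(v = matrix(seq_len(nc), nr, nc)))
  structure(list(
    F = F,
    descriptors = data.frame(layer = "v", class = classes,
                             param = NA_real_),
    cells = seq_len(nc), classes = unique(classes), hinge_knots = 0L,
    stack = stack), class = "maxent_features")
}

# independent generic convex-optimizer oracle for the maxent objective
# J(lambda) = -lambda.pmean + logZ(lambda) + sum(beta |lambda|)
maxent_objective_oracle <- function(F, pmean, beta, start = NULL) {
  obj <- function(l) {
    eta <- as.numeric(F %*% l)
    mx <- max(eta)
    -sum(l * pmean) + mx + log(sum(exp(eta - mx))) + sum(beta * abs(l))
  }
  start <- start %||% rep(0, ncol(F))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 50000, reltol = 1e-14))
  list(lambda = fit$par, objective = fit$value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# subset of an occurrence set by record index
occ_subset <- function(o, idx) {
  structure(list(species = o$species, x = o$x[idx], y = o$y[idx],
                 source = o$source[idx], row = o$row[idx], col = o$col[idx]),
            class = "occurrence_set")
}

# brute-force pair-counting AUC oracle (wins + half ties)
auc_oracle <- function(pres, bg) {
  wins <- 0
  for (p in pres) for (b in bg)
    wins <- wins + (p > b) + 0.5 * (p == b)
  wins / (length(pres) * length(bg))
}
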