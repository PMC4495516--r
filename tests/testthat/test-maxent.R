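# Fitting and transform behaviour of the maximum-entropy core.

fit_rows <- nichemax:::fit_maxent_rows

test_that("with no features the fitted distribution is exactly uniform", {
  stk <- raster_stack(list(t = matrix(rnorm(64), 8, 8)), cellsize = 90)
  f <- build_features(stk, sample_size = 14, feature_classes = character(0))
  expect_equal(ncol(f$F), 0)
  m <- fit_rows(f, c(1L, 5L))
  expect_equal(m$raw, rep(1 / 64, 64), tolerance = 1e-12)
  expect_equal(m$H, log(64), tolerance = 1e-10)
  # logistic of the uniform model is 0.5 everywhere
  expect_equal(predict(m, type = "logistic", as_surface = FALSE),
               rep(0.5, 64), tolerance = 1e-10)
})

test_that("with beta = 0 a single binary feature matches the presence mean exactly", {
  # background of 10 cells, feature = 1 on 4 of them; presences hit the
  # feature cell with mean 0.75
  F <- cbind(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  f <- manual_features(F)
  pidx <- c(1L, 2L, 3L, 5L)                 # presence mean 0.75
  m <- fit_rows(f, pidx, beta = 0)
  expect_equal(sum(m$raw * F[, 1]), 0.75, tolerance = 1e-6)

  # independent 1-D root-finding oracle for lambda:
  # E_lambda[f] = 4 e^l / (4 e^l + 6) = 0.75  =>  l = log(4.5)
  g <- function(l) 4 * exp(l) / (4 * exp(l) + 6) - 0.75
  l_star <- uniroot(g, c(-10, 10), tol = 1e-12)$root
  expect_equal(unname(coef(m)), l_star, tolerance = 1e-4)
  expect_equal(l_star, log(4.5), tolerance = 1e-9)
})

test_that("beta = 0 feature expectations match presence means on generic features", {
  set.seed(31)
  F <- matrix(runif(40 * 3), 40, 3)
  f <- manual_features(F, classes = c("linear", "quadratic", "linear"))
  pidx <- sample(40L, 12L)
  m <- fit_rows(f, pidx, beta = 0)
  expect_equal(as.numeric(crossprod(F, m$raw)),
               unname(colMeans(F[pidx, ])), tolerance = 1e-6)
})

test_that("the fit matches a generic convex-optimizer oracle on small problems", {
  set.seed(17)
  for (rep in 1:3) {
    N <- sample(5:10, 1)
    p <- sample(2:3, 1)
    F <- matrix(runif(N * p), N, p)
    f <- manual_features(F, classes = rep("linear", p))
    pidx <- sample(N, 3)
    beta <- 0.5
    m <- fit_rows(f, pidx, beta = beta)
    oracle <- maxent_objective_oracle(F, colMeans(F[pidx, , drop = FALSE]),
                                      rep(beta, p))
    expect_equal(m$objective, oracle$objective, tolerance = 1e-4)
  }
})

test_that("raw probabilities sum to one and the logistic transform is monotone", {
  scen <- gradient_study_scenario(seed = 3, n_rows = 30, n_cols = 30,
                                  n = c(25L, 20L, 16L, 12L))
  for (nm in c("species_a", "species_d")) {
    m <- maxent(scen$stack, scen$occurrences[[nm]])
    expect_equal(sum(m$raw), 1, tolerance = 1e-8)
    raw <- predict(m, type = "raw", as_surface = FALSE)
    logi <- predict(m, type = "logistic", as_surface = FALSE)
    expect_equal(order(raw), order(logi))
    expect_true(all(logi > 0 & logi < 1))
    # entropy is recomputable from the raw surface
    expect_equal(m$H, -sum(raw * log(raw)), tolerance = 1e-6)
  }
})

test_that("the logistic transform reproduces hand-computed toy values", {
  raw <- c(0.5, 0.3, 0.2)
  H <- -sum(raw * log(raw))
  fake <- structure(list(raw = raw, H = H), class = "maxent")
  got <- predict(fake, type = "logistic", as_surface = FALSE)
  expect_equal(got, exp(H) * raw / (1 + exp(H) * raw), tolerance = 1e-12)
})

test_that("a frozen-scale shift in one feature column leaves raw prediction unchanged", {
  set.seed(41)
  F <- matrix(runif(30 * 2), 30, 2)
  f <- manual_features(F, classes = c("linear", "linear"))
  m <- fit_rows(f, c(2L, 9L, 17L), beta = 0.1)
  f_shift <- f
  f_shift$F[, 1] <- f_shift$F[, 1] + 0.37
  expect_equal(predict(m, features = f_shift, type = "raw", as_surface = FALSE),
               predict(m, features = f, type = "raw", as_surface = FALSE),
               tolerance = 1e-12)
})

test_that("stronger regularization shrinks the total weight mass", {
  scen <- gradient_study_scenario(seed = 2, n_rows = 25, n_cols = 25,
                                  n = c(25L, 20L, 16L, 12L))
  o <- scen$occurrences$species_a
  f <- build_features(scen$stack, sample_size = length(o))
  l1 <- vapply(c(0.5, 1, 2, 5), function(mult)
    sum(abs(coef(maxent(f, o, beta_multiplier = mult)))), numeric(1))
  expect_true(all(diff(l1) <= 1e-8))
})

test_that("the minimum-training-presence threshold gives zero training omission", {
  stk <- raster_stack(list(v = matrix(0, 3, 3)), cellsize = 10)
  surf <- matrix(c(0.42, 0.31, 0.77, 0.1, 0.2, 0.9, 0.5, 0.6, 0.05), 3, 3)
  occ <- occ_at_cells(stk, c(1, 2, 3), c(1, 1, 1))
  expect_equal(mtp_threshold(surf, occ), min(0.42, 0.31, 0.77))
  occ1 <- occ_at_cells(stk, 2, 1)
  expect_equal(mtp_threshold(surf, occ1), surf[2, 1])

  # on a fitted model: binary map at the threshold contains every presence
  scen <- gradient_study_scenario(seed = 5, n_rows = 25, n_cols = 25,
                                  n = c(25L, 20L, 16L, 12L))
  m <- maxent(scen$stack, scen$occurrences$species_b)
  s <- predict(m)
  thr <- mtp_threshold(m)
  rng <- binarize(s, thr, cellsize = 90)
  o <- scen$occurrences$species_b
  expect_true(all(rng$cells[cbind(o$row, o$col)]))
})

test_that("cross-validation folds partition presences into near-equal parts", {
  scen <- gradient_study_scenario(seed = 4, n_rows = 30, n_cols = 30,
                                  n = c(38L, 20L, 16L, 12L))
  o <- scen$occurrences$species_a       # n = 38
  f <- build_features(scen$stack, sample_size = 38)
  cv <- crossvalidate(f, o, k = 10, seed = 9)
  sizes <- sort(tabulate(cv$folds))
  expect_equal(sizes, c(3, 3, rep(4, 8)))       # 38 = 8*4 + 2*3
  # held-out sets partition the presence set
  held <- unlist(cv$test_rows)
  expect_setequal(held, nichemax:::presence_rows(f, o))
  expect_equal(length(held), 38)
  # deterministic given the seed
  cv2 <- crossvalidate(f, o, k = 10, seed = 9)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$mean_test_auc, mean(cv$test_auc))

  expect_warning(cv3 <- crossvalidate(f, occ_subset(o, 1:5), k = 10, seed = 1),
                 "leave-one-out")
  expect_equal(cv3$k, 5)
})

test_that("models serialize to JSON and back with identical predictions", {
  scen <- gradient_study_scenario(seed = 6, n_rows = 20, n_cols = 20,
                                  n = c(20L, 16L, 14L, 12L))
  m <- maxent(scen$stack, scen$occurrences$species_c)
  path <- withr::local_tempfile(fileext = ".json")
  write_maxent_json(m, path)
  m2 <- read_maxent_json(path, scen$stack)
  expect_equal(unname(coef(m2)), unname(coef(m)), tolerance = 1e-12)
  expect_equal(m2$H, m$H, tolerance = 1e-12)
  expect_equal(predict(m2), predict(m), tolerance = 1e-10)
})

test_that("presences off the background are rejected", {
  m <- matrix(rnorm(25), 5, 5); m[1, 1] <- NA
  stk <- raster_stack(list(t = m), cellsize = 10)
  f <- build_features(stk, sample_size = 5)
  occ <- structure(list(species = "sp", x = 5, y = 45, source = "s",
                        row = c(1L, 2L), col = c(1L, 2L)),
                   class = "occurrence_set")
  expect_error(maxent(f, occ), "not background")
})
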