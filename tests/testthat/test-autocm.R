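fresh_model <- function(N, C = N, eps = 0.01) {
  structure(list(v = rep(eps, N), w = matrix(eps, N, N), C = C,
                 config = autocm_config(C = C, epsilon = eps)),
            class = "autocm")
}

test_that("forward pass contracts signals as specified", {
  m <- fresh_model(4)
  fp <- autocm_forward(m, rep(0, 4))
  expect_identical(fp$hidden, rep(0, 4))
  expect_identical(fp$output, rep(0, 4))

  # N = 1 closed form with m_s = 1, v = w = eps
  eps <- 0.01; C <- 2
  m1 <- fresh_model(1, C = C, eps = eps)
  fp1 <- autocm_forward(m1, 1)
  mh <- 1 - eps / C
  expect_equal(fp1$hidden, mh)
  expect_equal(fp1$output, mh * (1 - eps * mh / C^2))

  # fully saturated v kills the hidden layer regardless of input
  msat <- fresh_model(3)
  msat$v <- rep(msat$C, 3)
  expect_identical(autocm_forward(msat, c(0.2, 0.9, 1))$hidden, rep(0, 3))

  expect_error(autocm_forward(m, rep(0.5, 5)), "does not match")
})

test_that("learning deltas are zero at zero input and non-negative in general", {
  m <- fresh_model(5)
  d0 <- autocm_update(m, rep(0, 5))
  expect_identical(d0$dv, rep(0, 5))
  expect_identical(max(abs(d0$dw)), 0)

  set.seed(1)
  for (k in 1:25) {
    N <- sample(2:6, 1)
    m <- fresh_model(N, C = N)
    m$v <- runif(N, 0, N * 0.99)
    m$w <- matrix(runif(N * N, 0, N * 0.99), N, N)
    d <- autocm_update(m, runif(N))
    expect_true(all(d$dv >= 0))
    expect_true(all(d$dw >= 0))
  }

  # N = 1, m_s = 1: dv = (v/C)(1 - v/C), maximal at v = C/2
  C <- 2
  dv_at <- function(v) {
    m <- fresh_model(1, C = C)
    m$v <- v
    autocm_update(m, 1)$dv
  }
  expect_equal(dv_at(0.6), (0.6 / C) * (1 - 0.6 / C))
  expect_true(dv_at(C / 2) > dv_at(0.3) && dv_at(C / 2) > dv_at(1.7))
})

test_that("an all-zero dataset is a fixed point of training", {
  X <- matrix(0, 10, 4)
  expect_silent(m <- autocm_train(X))
  expect_identical(m$epochs_run, 1L)
  expect_true(m$converged)
  expect_identical(unname(m$v), rep(0.01, 4))
  expect_identical(max(abs(m$w - 0.01)), 0)
})

test_that("vectorized training matches the scalar-recursion oracle exactly", {
  for (seed in c(2, 7)) {
    X <- random_scaled_matrix(12, 4, seed)
    m <- autocm_train(X)
    o <- oracle_train(X)
    expect_equal(unname(m$v), o$v, tolerance = 1e-12)
    expect_equal(unname(m$w), o$w, tolerance = 1e-12)
    expect_identical(m$epochs_run, o$epochs)
  }
})

test_that("a duplicated column attains the maximal association with its twin", {
  X <- random_scaled_matrix(30, 4, seed = 4)
  X[, 2] <- X[, 1]  # column B duplicates column A
  m <- autocm_train(X)
  ws <- symmetrize(m$w)
  expect_true(all(ws[1, 2] >= ws[1, 3:4]))
  expect_true(all(ws[1, 2] >= ws[2, 3:4]))
  # and the scalar oracle agrees on the whole matrix
  o <- oracle_train(X)
  expect_equal(unname(m$w), o$w, tolerance = 1e-12)
})

test_that("v grows strictly and monotonically toward C on a repeated record", {
  # iterate the 1-D recursion v <- v + (m_s - m_h) (1 - v/C) directly
  C <- 2
  m <- fresh_model(1, C = C)
  traj <- numeric(200)
  for (k in seq_along(traj)) {
    d <- autocm_update(m, 0.7)
    m$v <- m$v + d$dv
    m$w <- m$w + d$dw
    traj[k] <- m$v
  }
  # strictly increasing until the approach to C exhausts double precision
  growing <- traj < C - 1e-9
  expect_true(all(diff(traj[growing]) > 0))
  expect_true(all(diff(traj) >= 0))
  expect_true(all(traj <= C))
  expect_lt(C - traj[length(traj)], 1e-3)
})

test_that("weights stay within [0, C] and grow monotonically across epochs", {
  X <- random_scaled_matrix(25, 6, seed = 11)
  prev <- NULL
  for (k in 1:8) {
    m <- suppressWarnings(autocm_train(X, autocm_config(max_epochs = k)))
    expect_true(all(m$v >= 0 & m$v <= m$C))
    expect_true(all(m$w >= 0 & m$w <= m$C))
    if (!is.null(prev)) {
      expect_true(all(m$v - prev$v >= 0))
      expect_true(all(m$w - prev$w >= 0))
    }
    prev <- m
  }
})

test_that("training is deterministic: identical runs give bit-identical models", {
  X <- random_scaled_matrix(40, 8, seed = 21)
  m1 <- autocm_train(X)
  m2 <- autocm_train(X)
  expect_identical(m1$v, m2$v)
  expect_identical(m1$w, m2$w)
  expect_identical(m1$trace, m2$trace)
})

test_that("record order perturbs online weights only marginally; batch is order-invariant", {
  # structured study-sized fixture: order effects must not disturb the
  # association structure the map is built from
  X <- assemble_dataset(generate_cohort(default_ms_design(), seed = 7))$records
  set.seed(99)
  Xp <- X[sample(nrow(X)), ]

  m1 <- autocm_train(X)
  m2 <- autocm_train(Xp)
  off <- symmetrize(m1$w)
  diag(off) <- NA
  scale <- max(off, na.rm = TRUE)
  # order effects are set by the saturation transient, not the convergence
  # tolerance: small relative to the weight scale, rank-preserving
  expect_lt(max(abs(m1$w - m2$w)), 0.2 * scale)
  ut <- upper.tri(m1$w)
  expect_gt(cor(m1$w[ut], m2$w[ut], method = "spearman"), 0.99)

  cfg <- autocm_config(update_mode = "batch")
  b1 <- autocm_train(X, cfg)
  b2 <- autocm_train(Xp, cfg)
  expect_equal(b1$w, b2$w, tolerance = 1e-12)

  # sorted-by-id record order makes even online runs row-order invariant
  rownames(X) <- sprintf("r%03d", seq_len(nrow(X)))
  Xp <- X[sample(nrow(X)), ]
  cfg_sorted <- autocm_config(record_order = "sorted-by-id")
  expect_identical(autocm_train(X, cfg_sorted)$w, autocm_train(Xp, cfg_sorted)$w)
})

test_that("a latent-coupled pair attains the maximum off-diagonal link strength", {
  for (seed in 1:20) {
    X <- separation_fixture(seed)
    ls <- link_strengths(autocm_train(X))
    diag(ls) <- NA
    expect_identical(ls["V1", "V2"], max(ls, na.rm = TRUE),
                     label = paste("link strength of the coupled pair, seed", seed))
  }
})

test_that("symmetrization folds a square matrix as requested", {
  w <- matrix(c(1, 0.4, 0.6, 2), 2, 2)
  expect_identical(symmetrize(w)[1, 2], 0.5)
  expect_identical(symmetrize(w)[2, 1], 0.5)
  expect_identical(symmetrize(w, "max")[1, 2], 0.6)
  s <- symmetrize(matrix(runif(25), 5, 5))
  expect_identical(max(abs(s - t(s))), 0)
  sym_in <- symmetrize(matrix(runif(16), 4, 4))
  expect_identical(symmetrize(sym_in), sym_in)
  expect_error(symmetrize(matrix(1, 2, 3)), "square")
})

test_that("distances invert weights monotonically and respect the bounds", {
  m <- autocm_train(random_scaled_matrix(30, 5, seed = 41))
  d <- autocm_distances(m)
  ws <- symmetrize(m$w)
  expect_identical(unname(diag(d)), rep(0, 5))
  expect_identical(max(abs(d - t(d))), 0)
  expect_true(all(d >= 0 & d <= m$C))
  ut <- which(upper.tri(d), arr.ind = TRUE)
  ord_w <- order(ws[ut])
  ord_d <- order(d[ut], decreasing = TRUE)
  expect_identical(ord_w, ord_d)

  # endpoints via a handcrafted model
  mm <- fresh_model(2, C = 3)
  mm$w <- matrix(c(0, 3, 3, 0), 2, 2)
  expect_identical(autocm_distances(mm)[1, 2], 0)
  mm$w <- matrix(0, 2, 2)
  expect_identical(autocm_distances(mm)[1, 2], 3)
  mm$w <- matrix(5, 2, 2)  # violates the invariant
  expect_error(autocm_distances(mm), "consistency")
})

test_that("link strengths lie in [0, 1] and complement the distances", {
  for (seed in 1:10) {
    m <- autocm_train(random_scaled_matrix(20, 6, seed = seed))
    ls <- link_strengths(m)
    d <- autocm_distances(m)
    expect_true(all(ls >= 0 & ls <= 1))
    off <- upper.tri(ls)
    expect_equal(ls[off] + d[off] / m$C, rep(1, sum(off)))
  }
  # relative normalization maps the strongest pair to exactly 1
  m <- autocm_train(separation_fixture(3),
                    autocm_config(ls_normalization = "max"))
  ls <- link_strengths(m)
  diag(ls) <- NA
  expect_identical(max(ls, na.rm = TRUE), 1)
})

test_that("models serialize to JSON and back without loss", {
  m <- autocm_train(random_scaled_matrix(15, 5, seed = 51))
  f <- tempfile(fileext = ".json")
  write_autocm(m, f)
  m2 <- read_autocm(f)
  expect_identical(m2$v, m$v)
  expect_identical(m2$w, m$w)
  expect_identical(m2$C, m$C)
  expect_identical(m2$trace, m$trace)
  expect_identical(m2$converged, m$converged)
  expect_identical(m2$variables, m$variables)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(autocm_config(C = 0.5), ">= 1")
  expect_error(autocm_config(C = 2, epsilon = 3), "epsilon")
  expect_error(autocm_config(epsilon = 0), "epsilon")
  expect_error(autocm_config(tolerance = 0), "tolerance")
  expect_error(autocm_config(max_epochs = 0), "max_epochs")
  expect_error(autocm_train(matrix(c(0.5, 1.2), 1, 2)), "\\[0, 1\\]")
  expect_warning(autocm_train(random_scaled_matrix(10, 3, 1),
                              autocm_config(max_epochs = 2)),
                 "did not converge")
})
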