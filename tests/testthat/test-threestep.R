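test_that("identity kernels decouple the solution entrywise", {
  set.seed(2)
  y <- as.array(rand_tensor(5, 3))
  dimnames(y) <- NULL
  lam <- c(0.3, 0.7, 2)
  fit <- threestep(y, kd = diag(5), ke = diag(3), lambda = lam)
  expect_equal(coef(fit), y / prod(1 + lam), tolerance = 1e-12)
})

test_that("solver matches the dense Kronecker-expanded solve across lambda", {
  set.seed(4)
  lams <- expand.grid(l1 = c(1e-3, 1, 1e3), l2 = c(1e-3, 1, 1e3),
                      l3 = c(1e-3, 1, 1e3))
  for (cfg in list(c(4, 3), c(6, 4))) {
    y <- as.array(rand_tensor(cfg[1], cfg[2], p = 0.3))
    kd <- rand_psd(cfg[1])
    ke <- rand_psd(cfg[2])
    for (r in seq_len(nrow(lams))) {
      lam <- as.numeric(lams[r, ])
      fit <- threestep(y, kd = kd, ke = ke, lambda = lam)
      a_ref <- dense_solve_threestep(y, kd, ke, lam)
      rel <- sqrt(sum((coef(fit) - a_ref)^2)) / sqrt(sum(a_ref^2))
      expect_lt(rel, 1e-8)
      expect_lt(fit$residual, 1e-8)
    }
  }
})

test_that("prediction is the triple contraction of the defining equation", {
  set.seed(6)
  y <- as.array(rand_tensor(4, 3, p = 0.4))
  kd <- rand_psd(4)
  ke <- rand_psd(3)
  fit <- threestep(y, kd = kd, ke = ke, lambda = c(0.1, 0.2, 0.3))
  # similarity vectors equal to training rows reproduce fitted values
  expect_equal(predict(fit, kd[2, ], kd[3, ], ke[1, ]),
               fitted(fit)[2, 3, 1], tolerance = 1e-10)
  # zero effect-similarity vector gives zero by linearity
  expect_equal(predict(fit, kd[1, ], kd[2, ], rep(0, 3)), 0)
  # random queries match a triple-loop evaluation
  for (q in 1:5) {
    v1 <- runif(4); v2 <- runif(4); v3 <- runif(3)
    expect_equal(predict(fit, v1, v2, v3),
                 naive_predict(coef(fit), v1, v2, v3), tolerance = 1e-10)
  }
  expect_error(predict(fit, runif(3), kd[1, ], ke[1, ]), "length 4")
})

test_that("fitted tensor interpolates as lambda -> 0 and vanishes as lambda3 -> Inf", {
  set.seed(8)
  y <- as.array(rand_tensor(5, 4, p = 0.4))
  dimnames(y) <- NULL
  kd <- rand_psd(5) + diag(5)        # full rank
  ke <- rand_psd(4) + diag(4)
  f0 <- fitted(threestep(y, kd = kd, ke = ke, lambda = c(1e-10, 1e-10, 1e-10)))
  expect_equal(f0, y, tolerance = 1e-6)
  finf <- fitted(threestep(y, kd = kd, ke = ke, lambda = c(0.1, 0.1, 1e12)))
  expect_lt(max(abs(finf)), 1e-9)
  # fitted equals predict() on the training grid
  fit <- threestep(y, kd = kd, ke = ke, lambda = c(0.5, 0.2, 0.9))
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-10)
})

test_that("hat matrix matches the direct solve and stays a contraction", {
  expect_equal(hat_matrix(diag(8), 1), diag(8) / 2)
  set.seed(10)
  k <- rand_psd(8)
  for (lam in c(0.01, 1, 50)) {
    h <- hat_matrix(k, lam)
    expect_equal(h, k %*% solve(k + diag(lam, 8)), tolerance = 1e-10)
    ev <- eigen(h, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-12 & ev < 1))
  }
  kf <- k + diag(8)
  expect_equal(hat_matrix(kf, 1e-12), diag(8), tolerance = 1e-6)
})

test_that("symmetric labels with lambda1 = lambda2 give symmetric fits", {
  set.seed(12)
  y <- rand_tensor(6, 3, p = 0.3)
  kd <- rand_psd(6)
  ke <- rand_psd(3)
  f <- fitted(threestep(y, kd = kd, ke = ke, lambda = c(0.2, 0.2, 0.5)))
  expect_lt(max(abs(f - aperm(f, c(2, 1, 3)))), 1e-12)
})

test_that("identity effect kernel with lambda3 = 0 decouples into two-step fits", {
  set.seed(15)
  y <- as.array(rand_tensor(6, 4, p = 0.3))
  kd <- rand_psd(6)
  lam <- c(0.3, 0.08, 0)
  f <- fitted(threestep(y, kd = kd, ke = diag(4), lambda = lam))
  h1 <- kd %*% solve(kd + diag(lam[1], 6))
  h2 <- kd %*% solve(kd + diag(lam[2], 6))
  for (k in 1:4) {
    twostep <- h1 %*% y[, , k] %*% t(h2)   # standalone pairwise smoother
    expect_equal(f[, , k], twostep, tolerance = 1e-8)
  }
})

test_that("fit norm shrinks monotonically in each regularization parameter", {
  set.seed(16)
  y <- as.array(rand_tensor(6, 4, p = 0.3))
  kd <- rand_psd(6)
  ke <- rand_psd(4)
  grid <- c(1e-3, 1e-1, 1e1, 1e3)
  base <- c(0.1, 0.1, 0.1)
  for (mode in 1:3) {
    norms <- sapply(grid, function(l) {
      lam <- base; lam[mode] <- l
      sqrt(sum(fitted(threestep(y, kd = kd, ke = ke, lambda = lam))^2))
    })
    expect_true(all(diff(norms) <= 1e-10))
  }
})

test_that("singular shifted Gram matrices are reported with their mode", {
  y <- array(0, c(3, 3, 2))
  expect_error(threestep(y, kd = matrix(0, 3, 3), ke = diag(2),
                         lambda = c(0, 1, 1)), "mode 1")
  expect_error(threestep(y, kd = diag(3), ke = matrix(0, 2, 2),
                         lambda = c(1, 1, 0)), "mode 3")
})

test_that("model archives round-trip through a single file", {
  set.seed(17)
  sim <- simulate_polypharmacy(10, 4, seed = 17)
  fit <- suppressWarnings(threestep(sim$tensor, features = sim$features,
                                    lambda = c(0.1, 0.1, 0.2)))
  path <- tempfile(fileext = ".rds")
  write_threestep(fit, path)
  back <- read_threestep(path)
  expect_equal(coef(back), coef(fit), tolerance = 1e-10)
  expect_equal(fitted(back), fitted(fit), tolerance = 1e-10)
  expect_equal(back$lambda, fit$lambda)
  unlink(path)
})
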