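test_that("superposing a model onto itself or a rigid copy gives RMSD 0", {
  h <- make_helix(30)
  corr <- build_correspondence(h, h)
  self <- kabsch_superpose(corr, h, h)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)

  moved <- transform_model(h, rotation_z_test(90), c(5, 0, 0))
  fit <- kabsch_superpose(build_correspondence(h, moved), h, moved)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  # recovered rotation is orthonormal with det +1
  expect_equal(t(fit$rotation) %*% fit$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-6)
})

test_that("Kabsch agrees with the quaternion oracle on noisy helices", {
  set.seed(2024)
  h <- make_helix(30)
  ca_ref <- as.matrix(h$atoms[h$atoms$elety == "CA", c("x", "y", "z")])
  for (i in 1:5) {
    noisy <- h
    xyz <- as.matrix(noisy$atoms[, c("x", "y", "z")]) +
      matrix(rnorm(3 * nrow(noisy$atoms), sd = 0.5), ncol = 3)
    noisy$atoms$x <- xyz[, 1]; noisy$atoms$y <- xyz[, 2]; noisy$atoms$z <- xyz[, 3]
    fit <- kabsch_superpose(build_correspondence(h, noisy), h, noisy)
    ca_mob <- as.matrix(noisy$atoms[noisy$atoms$elety == "CA",
                                    c("x", "y", "z")])
    expect_equal(fit$rmsd, quat_superpose(ca_ref, ca_mob)$rmsd,
                 tolerance = 1e-6)
  }
})

test_that("the reported transform reproduces the RMSD recomputed naively", {
  set.seed(8)
  tc <- make_toy_complex(2, 25, perturbation = list(type = "gaussian",
                                                    sigma = 0.8), seed = 8)
  corr <- build_correspondence(tc$native, tc$model)
  fit <- kabsch_superpose(corr, tc$native, tc$model)
  ca_n <- tc$native$atoms[tc$native$atoms$elety == "CA", ]
  ca_m <- tc$model$atoms[tc$model$atoms$elety == "CA", ]
  xyz <- sweep(as.matrix(ca_m[, c("x", "y", "z")]) %*% fit$rotation, 2,
               fit$translation, "+")
  naive <- sqrt(mean(rowSums((xyz - as.matrix(ca_n[, c("x", "y", "z")]))^2)))
  expect_equal(fit$rmsd, naive, tolerance = 1e-9)
})

test_that("RMSD is symmetric and invariant under rigid pre-transforms", {
  set.seed(31)
  a <- make_helix(20)
  b <- a
  xyz <- as.matrix(b$atoms[, c("x", "y", "z")]) +
    matrix(rnorm(3 * nrow(b$atoms), sd = 0.4), ncol = 3)
  b$atoms$x <- xyz[, 1]; b$atoms$y <- xyz[, 2]; b$atoms$z <- xyz[, 3]
  r_ab <- kabsch_superpose(build_correspondence(a, b), a, b)$rmsd
  r_ba <- kabsch_superpose(build_correspondence(b, a), b, a)$rmsd
  expect_equal(r_ab, r_ba, tolerance = 1e-9)
  for (i in 1:3) {
    R <- random_rotation()
    b2 <- transform_model(b, R, rnorm(3, sd = 10))
    expect_equal(kabsch_superpose(build_correspondence(a, b2), a, b2)$rmsd,
                 r_ab, tolerance = 1e-9)
  }
})

test_that("Kabsch matches brute-force optima and rejects degenerate input", {
  # <= 5 points: quaternion closed form is the independent optimum
  set.seed(77)
  for (n in 3:5) {
    X <- matrix(rnorm(3 * n, sd = 3), ncol = 3)
    Y <- X %*% random_rotation() + matrix(rnorm(3 * n, sd = 0.2), ncol = 3)
    expect_equal(kabsch_fit(X, Y)$rmsd, quat_superpose(X, Y)$rmsd,
                 tolerance = 1e-6)
  }
  expect_error(kabsch_fit(diag(3)[1:2, ], diag(3)[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line, line), "collinear|degenerate")
})

test_that("outlier rejection removes planted outliers and refits", {
  h <- make_helix(30)
  bad <- h
  sel <- bad$atoms$resno == 15 & bad$atoms$elety == "CA"
  bad$atoms$x[sel] <- bad$atoms$x[sel] + 25
  corr <- build_correspondence(h, bad)
  plain <- kabsch_superpose(corr, h, bad)
  cleaned <- kabsch_superpose(corr, h, bad,
                              outlier_rejection = list(cutoff = 2, max_cycles = 5))
  expect_gt(plain$rmsd, 1)
  expect_equal(cleaned$rmsd, 0, tolerance = 1e-6)
  expect_equal(nrow(cleaned$rejected), 1L)
  expect_equal(cleaned$n_pairs, 29L)
})

test_that("removing a pair never increases the optimal residual sum", {
  set.seed(55)
  X <- matrix(rnorm(45), ncol = 3)
  Y <- X %*% random_rotation() + matrix(rnorm(45, sd = 0.5), ncol = 3)
  full <- kabsch_fit(X, Y)
  sse_full <- full$rmsd^2 * nrow(X)
  for (drop in 1:5) {
    sub <- kabsch_fit(X[-drop, ], Y[-drop, ])
    sse_sub <- sub$rmsd^2 * (nrow(X) - 1)
    expect_lte(sse_sub, sse_full + 1e-9)
  }
})

test_that("rmsd_report summarizes per-subunit results", {
  mk <- function(r) structure(list(rmsd = r, n_pairs = 10L,
                                   rejected = data.frame()),
                              class = "superposition_result")
  rep3 <- rmsd_report(list(a = mk(0.3), b = mk(0.5), c = mk(1.3)))
  expect_equal(unname(rep3$summary), c(0.3, 1.3, 0.5))
  rep1 <- rmsd_report(list(solo = mk(0.7)))
  expect_equal(unname(rep1$summary), c(0.7, 0.7, 0.7))
})
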