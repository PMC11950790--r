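test_that("generation is byte-identical for a fixed seed", {
  r1 <- make_tm_sequence("s", length = 200, seed = 99)
  r2 <- make_tm_sequence("s", length = 200, seed = 99)
  expect_identical(r1, r2)

  t1 <- make_toy_complex(3, 25, perturbation = list(type = "gaussian",
                                                    sigma = 0.5), seed = 7)
  t2 <- make_toy_complex(3, 25, perturbation = list(type = "gaussian",
                                                    sigma = 0.5), seed = 7)
  d <- withr::local_tempdir()
  write_structure_pdb(t1$model, file.path(d, "m1.pdb"))
  write_structure_pdb(t2$model, file.path(d, "m2.pdb"))
  expect_identical(readLines(file.path(d, "m1.pdb")),
                   readLines(file.path(d, "m2.pdb")))
})

test_that("hydrophobic bias controls the substitutable TM density", {
  all_h <- make_tm_sequence("b1", length = 120, hydrophobic_bias = 1,
                            seed = 1)
  r <- apply_qty_code(all_h)
  expect_equal(r$tm_variation_pct, 100.00)

  none <- make_tm_sequence("b0", length = 120, hydrophobic_bias = 0, seed = 1)
  expect_equal(nrow(apply_qty_code(none)$substitutions), 0L)

  # binomial expectation at bias 0.5 over 1000 residues
  half <- make_tm_sequence("b5", length = 1000, tm_fraction = 0.5,
                           hydrophobic_bias = 0.5, seed = 2)
  tmv <- apply_qty_code(half)$tm_variation_pct
  n_tm <- sum(half$tm_segments$end - half$tm_segments$start + 1)
  se <- 100 * sqrt(0.25 / n_tm)
  expect_lt(abs(tmv - 50), 4 * se)
})

test_that("ideal helices have canonical geometry", {
  h <- make_helix(30)
  ca <- as.matrix(h$atoms[h$atoms$elety == "CA", c("x", "y", "z")])
  d <- sqrt(rowSums((ca[-1, ] - ca[-30, ])^2))
  expect_true(all(abs(d - 3.8) < 0.05))
  # 100 degrees/residue: 18 residues = 5 full turns, same helical phase
  expect_equal(ca[1, 1:2], ca[19, 1:2], tolerance = 1e-9)
  expect_equal(ca[19, 3] - ca[1, 3], 18 * 1.5, tolerance = 1e-9)

  corr <- build_correspondence(h, h)
  expect_equal(kabsch_superpose(corr, h, h)$rmsd, 0, tolerance = 1e-12)
})

test_that("toy-complex truth records predict downstream measurements", {
  # rigid: Kabsch recovers the inverse transform exactly
  tc <- make_toy_complex(2, 25, perturbation = list(type = "rigid",
                                                    angle_deg = 40,
                                                    shift = c(3, -2, 1)),
                         seed = 5)
  corr <- build_correspondence(tc$native, tc$model)
  fit <- kabsch_superpose(corr, tc$native, tc$model)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, t(tc$truth$rotation), tolerance = 1e-9)

  # ligand shift: LRMS equals the truth shift magnitude
  ls <- make_toy_complex(2, 25, perturbation = list(type = "ligand_shift",
                                                    shift = c(1, 2, 2)),
                         seed = 5)
  rr <- interface_rmsds(ls$native, ls$model, "A", "B",
                        build_correspondence(ls$native, ls$model))
  expect_equal(rr$lrms, ls$truth$expected_lrms, tolerance = 1e-9)
  expect_equal(ls$truth$expected_lrms, 3)

  # gaussian: fitted RMSD matches the sigma*sqrt((3m-6)/m) prediction
  g <- make_toy_complex(2, 50, perturbation = list(type = "gaussian",
                                                   sigma = 0.5), seed = 13)
  corr_g <- build_correspondence(g$native, g$model)
  fit_g <- kabsch_superpose(corr_g, g$native, g$model,
                            atom_set = c("N", "CA", "C", "O", "CB"))
  m <- length(fit_g$deviations)
  expect_gt(m, 400)
  predicted <- g$truth$sigma * sqrt((3 * m - 6) / m)
  expect_lt(abs(fit_g$rmsd - predicted) / predicted, 0.05)

  # loop deletion: correspondence trimming recovers exactly the survivors
  ld <- make_toy_complex(2, 30, perturbation = list(type = "loop_deletion",
                                                    fraction = 0.2), seed = 9)
  corr_ld <- build_correspondence(ld$native, ld$model)
  expect_equal(nrow(corr_ld$dropped_b), nrow(ld$truth$deleted_residues))
  expect_setequal(paste(corr_ld$dropped_b$chain, corr_ld$dropped_b$resno),
                  paste(ld$truth$deleted_residues$chain,
                        ld$truth$deleted_residues$resno))
  expect_equal(length(unique(paste(corr_ld$pairs$chain_a,
                                   corr_ld$pairs$resno_a))),
               60L - nrow(ld$truth$deleted_residues))
})
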