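test_that("residue contacts match a brute-force all-pairs scan", {
  tc <- make_toy_complex(2, 20, perturbation = list(type = "gaussian",
                                                    sigma = 0.3), seed = 4)
  cs <- native_contacts(tc$native, "A", "B")
  expect_gt(nrow(cs$pairs), 0)
  heavy <- function(ch) {
    a <- tc$native$atoms
    a[a$chain == ch & a$element != "H", ]
  }
  bf <- brute_contacts(heavy("A"), heavy("B"), 5)
  expect_setequal(paste(cs$pairs$resno_a, cs$pairs$resno_b),
                  paste(bf$resno_a, bf$resno_b))

  # far-apart chains and degenerate cutoff give empty sets
  far <- transform_model(make_helix(10, chain = "B"), diag(3), c(100, 0, 0))
  both <- structure_model(rbind(make_helix(10)$atoms, far$atoms), "far")
  expect_equal(nrow(native_contacts(both, "A", "B")$pairs), 0L)
  expect_equal(nrow(native_contacts(tc$native, "A", "B", cutoff = 0)$pairs), 0L)
  expect_error(native_contacts(tc$native, "A", "Z"), "missing")
})

test_that("Fnat is the preserved fraction and refuses empty native sets", {
  mk <- function(pairs) structure(list(pairs = pairs, cutoff = 5,
                                       chain_a = "A", chain_b = "B"),
                                  class = "contact_set")
  nat <- mk(data.frame(resno_a = 1:4, resno_b = 11:14))
  half <- mk(data.frame(resno_a = 1:2, resno_b = 11:12))
  expect_equal(fnat(nat, half), 0.5)
  expect_equal(fnat(nat, nat), 1.0)
  expect_equal(fnat(nat, mk(data.frame(resno_a = 9, resno_b = 9))), 0.0)
  expect_error(fnat(mk(nat$pairs[0, ]), nat), "undefined")
})

test_that("ligand and interface RMSDs follow the DockQ definitions", {
  tc <- make_toy_complex(2, 25, perturbation = list(type = "rigid",
                                                    angle_deg = 0,
                                                    shift = c(0, 0, 0)),
                         seed = 6)
  corr <- build_correspondence(tc$native, tc$model)
  rr <- interface_rmsds(tc$native, tc$model, "A", "B", corr)
  expect_equal(rr$lrms, 0, tolerance = 1e-9)
  expect_equal(rr$irms, 0, tolerance = 1e-9)

  # rigid ligand offset with fixed receptor: LRMS is exactly the shift
  shift <- make_toy_complex(2, 25,
                            perturbation = list(type = "ligand_shift",
                                                shift = c(0, 2, 0)), seed = 6)
  corr2 <- build_correspondence(shift$native, shift$model)
  rr2 <- interface_rmsds(shift$native, shift$model, "A", "B", corr2)
  expect_equal(rr2$lrms, 2.0, tolerance = 1e-9)
  expect_gt(rr2$irms, 0)
})

test_that("the DockQ formula and CAPRI bins are exact", {
  expect_equal(dockq_score(1, 0, 0), 1.0)
  expect_lt(dockq_score(0, 1e6, 1e6), 1e-6)
  # frozen closed-form arithmetic of the three-term formula
  expect_equal(dockq_score(0.5, 1.965, 0.905), 0.7274667, tolerance = 1e-4)

  expect_equal(capri_class(c(0.85, 0.712, 0.23, 0.2299, 0.80, 0.49)),
               c("High", "Medium", "Acceptable", "Incorrect", "High",
                 "Medium"))
})

test_that("scoring agrees with an independent DockQ oracle on random dimers", {
  set.seed(303)
  for (i in 1:12) {
    sigma <- runif(1, 0.1, 1.5)
    tc <- make_toy_complex(2, 20,
                           perturbation = list(type = "gaussian", sigma = sigma),
                           seed = 1000L + i)
    o <- oracle_dockq(tc$native, tc$model, "A", "B")
    corr <- build_correspondence(tc$native, tc$model)
    fn <- fnat(native_contacts(tc$native, "A", "B"),
               native_contacts(tc$model, "A", "B"))
    rr <- interface_rmsds(tc$native, tc$model, "A", "B", corr)
    expect_equal(fn, o$fnat, tolerance = 1e-9)
    expect_equal(rr$lrms, o$lrms, tolerance = 1e-6)
    expect_equal(rr$irms, o$irms, tolerance = 1e-6)
    expect_equal(dockq_score(fn, rr$lrms, rr$irms), o$dockq, tolerance = 1e-6)
  }
})

test_that("DockQ decreases monotonically with growing ligand displacement", {
  scores <- vapply(c(0, 0.5, 1, 2, 4, 8, 16), function(d) {
    tc <- make_toy_complex(2, 20,
                           perturbation = list(type = "ligand_shift",
                                               shift = c(0, d, 0)), seed = 12)
    corr <- build_correspondence(tc$native, tc$model)
    fn <- fnat(native_contacts(tc$native, "A", "B"),
               native_contacts(tc$model, "A", "B"))
    rr <- interface_rmsds(tc$native, tc$model, "A", "B", corr)
    dockq_score(fn, rr$lrms, rr$irms)
  }, numeric(1))
  expect_true(all(diff(scores) <= 1e-9))
  expect_equal(scores[1], 1.0)
})

test_that("score_complex enumerates only contacting pairs and self-scores 1", {
  # 3 chains in a row: A-B and B-C touch, A-C is 20 A away
  tc <- make_toy_complex(3, 20, perturbation = list(type = "gaussian",
                                                    sigma = 0.4), seed = 21)
  rep_self <- score_complex(tc$native, tc$native)
  expect_equal(rep_self$per_interface$dockq, rep(1, 2), tolerance = 1e-9)
  expect_equal(unname(rep_self$medians["dockq"]), 1.0, tolerance = 1e-9)
  expect_equal(rep_self$n_interfaces, 2L)
  expect_setequal(rep_self$per_interface$chain_pair, c("A-B", "B-C"))

  rep_mod <- score_complex(tc$native, tc$model)
  expect_true(all(rep_mod$per_interface$dockq >= 0 &
                    rep_mod$per_interface$dockq <= 1))
  expect_true(all(rep_mod$per_interface$capri_class ==
                    capri_class(rep_mod$per_interface$dockq)))

  # equal-sized chains: swapping the chain-map order leaves DockQ unchanged
  swapped <- score_complex(tc$native, tc$model,
                           chain_map = c(C = "C", B = "B", A = "A"))
  expect_equal(sort(rep_mod$per_interface$dockq),
               sort(swapped$per_interface$dockq), tolerance = 1e-9)
  expect_equal(rep_mod$overall_dockq, swapped$overall_dockq, tolerance = 1e-9)
})
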