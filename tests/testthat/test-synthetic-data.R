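test_that("Beta parameterisation round-trips the RSM with a closed form", {
  expect_equal(beta_rsm(2, 2), sqrt(0.3), tolerance = 1e-12)
  ab <- rsm_to_beta(sqrt(0.3), concentration = 4)
  expect_equal(unname(ab), c(2, 2), tolerance = 1e-8)

  for (target in c(0.45, 0.55, 0.65)) {
    ab <- rsm_to_beta(target)
    expect_equal(beta_rsm(ab["alpha"], ab["beta"]), target,
                 tolerance = 1e-8, ignore_attr = TRUE)
    # quadrature oracle on the realised profile
    q <- sqrt(stats::integrate(function(r) {
      dbeta(r, ab["alpha"], ab["beta"]) * r^2
    }, 0, 1, rel.tol = 1e-10)$value)
    expect_equal(q, target, tolerance = 1e-6)
  }
  expect_error(rsm_to_beta(1.0), "outside the attainable range")
  expect_error(rsm_to_beta(0.1), "outside the attainable range")
})

test_that("outlines realised from Beta profiles have the analytic RSM", {
  ol <- outline_from_profile(2.6, 1.9, wing_length = 30, n_vertices = 400)
  expect_equal(rsm_from_outline(ol), beta_rsm(2.6, 1.9),
               tolerance = 0.005 * beta_rsm(2.6, 1.9))
  ol2 <- outline_from_profile(2.6, 1.9, wing_length = 60, n_vertices = 400)
  expect_equal(rsm_from_outline(ol2), rsm_from_outline(ol),
               tolerance = 1e-9)
  expect_error(outline_from_profile(2, 2, 10, n_vertices = 3),
               "degenerate")
})

test_that("landmark placement is deterministic without noise and scales", {
  ol <- outline_from_profile(2, 2, wing_length = 20)
  l1 <- landmarks_from_outline(ol, noise_sd = 0)
  l2 <- landmarks_from_outline(ol, noise_sd = 0)
  expect_identical(l1$coords, l2$coords)
  expect_identical(l1$semilandmarks, c(11L, 12L))

  ol2 <- outline_from_profile(2, 2, wing_length = 40)
  l3 <- landmarks_from_outline(ol2, noise_sd = 0)
  expect_equal(centroid_size(l3) / centroid_size(l1), 2,
               tolerance = 1e-9)
})

test_that("GPA recovers the template from noisy digitised replicates", {
  set.seed(97)
  ol <- outline_from_profile(2, 2, wing_length = 1)
  truth <- landmarks_from_outline(ol, noise_sd = 0)
  noise_sd <- 0.01
  reps <- lapply(1:10, function(i) {
    landmarks_from_outline(ol, noise_sd = noise_sd)
  })
  sp <- gpa(reps, slide = FALSE)
  truth_scaled <- calomorph:::center_scale(truth$coords)
  rot <- calomorph:::procrustes_rotation(truth_scaled, sp$consensus)
  err <- sqrt(rowSums((truth_scaled %*% rot - sp$consensus)^2))
  # per-landmark consensus error at CLT scale (noise_sd relative to the
  # unit-centroid-size configuration)
  expect_lt(max(err), 3 * noise_sd / centroid_size(truth$coords) /
                       sqrt(10) * centroid_size(truth$coords) + 0.01)
  expect_lt(mean(err), 0.01)
})

test_that("simulated trees are bifurcating, seeded and sized as specified", {
  spec <- simulation_spec(seed = 5)
  tr <- simulate_tree(spec)
  expect_length(tr$tip.label, 37)
  expect_true(attr(tr, "bifurcating"))
  expect_equal(nrow(tr$edge), 2 * 37 - 2)   # Yule edge count
  expect_length(basal_clade(tr), 4)
  tr2 <- simulate_tree(simulation_spec(seed = 5))
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  tr3 <- simulate_tree(simulation_spec(seed = 6))
  expect_false(identical(ape::write.tree(tr), ape::write.tree(tr3)))
})

test_that("trait simulation honours its deterministic and null limits", {
  # no clade offset, no noise: RSM exactly linear in size; contrast
  # slope recovers the generating slope exactly
  spec0 <- simulation_spec(clade_offset = 0, size_shift_basal = 0,
                           residual_sd = 0, rsm_slope = -0.1, seed = 3)
  tr <- simulate_tree(spec0)
  tt <- simulate_traits(tr, spec0)
  fw <- tt[tt$wing == "fore", ]
  f <- suppressWarnings(polynomial_regression(fw$rsm_true,
                                              fw$log_size_true, 1))
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  cs <- contrast_set(tr, setNames(fw$log_size_true, fw$taxon),
                     setNames(fw$rsm_true, fw$taxon))
  expect_equal(contrast_regression(cs)$slope, -0.1, tolerance = 1e-10)

  # b = 0, delta = 0: contrast-slope test is a true null
  pv <- vapply(1:100, function(i) {
    sp <- simulation_spec(rsm_slope = 0, clade_offset = 0,
                          size_shift_basal = 0, seed = 5000 + i)
    trn <- simulate_tree(sp)
    tn <- simulate_traits(trn, sp)
    fwn <- tn[tn$wing == "fore", ]
    contrast_regression(
      contrast_set(trn, setNames(fwn$log_size_true, fwn$taxon),
                   setNames(fwn$rsm_true, fwn$taxon)))$p_value
  }, 0)
  expect_gt(mean(pv < 0.05), 0.005)
  expect_lt(mean(pv < 0.05), 0.12)
})

test_that("datasets are reproducible and within the specified design", {
  spec <- simulation_spec(n_taxa = 6, n_basal = 2, specimens_min = 5,
                          specimens_max = 10, n_vertices = 120,
                          n_strips = 200, seed = 77)
  d1 <- simulate_wing_dataset(spec)
  d2 <- simulate_wing_dataset(spec)
  expect_identical(d1$specimens, d2$specimens)
  expect_identical(d1$landmarks[[5]]$coords, d2$landmarks[[5]]$coords)

  expect_true(all(d1$traits$n_specimens >= 5 &
                  d1$traits$n_specimens <= 10))

  # measured RSM tracks the analytic per-specimen value across the cohort
  err <- vapply(seq_len(nrow(d1$specimens)), function(i) {
    id <- d1$specimens$specimen[i]
    abs(rsm_from_outline(d1$outlines[[id]], n_strips = 200) -
          d1$specimens$rsm_analytic[i]) / d1$specimens$rsm_analytic[i]
  }, 0)
  expect_lt(max(err), 0.01)
})

test_that("written datasets load back into an equivalent analysis input", {
  spec <- simulation_spec(n_taxa = 5, n_basal = 2, specimens_min = 3,
                          specimens_max = 3, n_vertices = 100,
                          n_strips = 100, seed = 13)
  ds <- simulate_wing_dataset(spec)
  dir <- withr::local_tempdir()
  write_wing_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  loaded <- calomorph:::load_wing_dataset(list(
    tree = file.path(dir, "tree.nwk"),
    tps_fore = file.path(dir, "landmarks_fore.tps"),
    tps_hind = file.path(dir, "landmarks_hind.tps"),
    traits = file.path(dir, "traits.csv"),
    outline_dir = file.path(dir, "outlines")))
  expect_setequal(loaded$specimens$specimen, ds$specimens$specimen)
  id <- ds$specimens$specimen[1]
  expect_equal(loaded$landmarks[[id]]$coords, ds$landmarks[[id]]$coords,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(rsm_from_outline(loaded$outlines[[id]], 100),
               rsm_from_outline(ds$outlines[[id]], 100), tolerance = 1e-9)
})
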