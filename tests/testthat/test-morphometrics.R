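test_that("centroid size is the root summed squared centroid distance", {
  sq <- rbind(c(-0.5, -0.5), c(0.5, -0.5), c(0.5, 0.5), c(-0.5, 0.5))
  expect_equal(centroid_size(sq), sqrt(2))
  cfg <- reference_config()
  expect_equal(centroid_size(cfg * 3), 3 * centroid_size(cfg))
  th <- 0.7; Q <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_equal(centroid_size(cfg %*% Q), centroid_size(cfg))
  expect_error(centroid_size(matrix(1, 4, 2)), "degenerate")
})

test_that("GPA removes position, scale and orientation exactly", {
  cfg <- reference_config()
  th <- pi / 2; Q <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  copy <- 3 * cfg %*% Q + 5
  sp <- gpa(list(landmark_set(cfg), landmark_set(copy)), slide = FALSE)
  expect_equal(procrustes_distance(cfg, copy), 0, tolerance = 1e-9)
  expect_equal(sp$aligned[[1]], sp$aligned[[2]], tolerance = 1e-9)
  expect_equal(sp$centroid_sizes[2] / sp$centroid_sizes[1], 3,
               tolerance = 1e-12)

  # single specimen: consensus is that configuration at unit size
  one <- gpa(list(landmark_set(cfg)), slide = FALSE)
  expect_equal(procrustes_distance(one$consensus, cfg), 0,
               tolerance = 1e-10)
})

test_that("Procrustes alignment matches a fine rotation grid search", {
  set.seed(7)
  A <- reference_config()
  B <- A + matrix(rnorm(24, 0, 0.1), 12, 2)
  expect_equal(procrustes_distance(A, B),
               grid_procrustes_distance(A, B, step = 0.001),
               tolerance = 1e-6)
})

test_that("GPA descends monotonically and its consensus is a fixed point", {
  set.seed(11)
  specs <- noisy_configs(reference_config(), 15, sd = 0.08)
  sp <- gpa(specs, slide = FALSE)
  expect_true(all(diff(sp$ss_trace) <= 1e-12))
  rerun <- gpa(lapply(sp$aligned, landmark_set), slide = FALSE)
  expect_lt(procrustes_distance(rerun$consensus, sp$consensus), 1e-8)
})

test_that("sliding semilandmarks never increases distance to consensus", {
  set.seed(13)
  specs <- noisy_configs(reference_config(), 12, sd = 0.05,
                         semis = c(4L, 9L))
  sp <- gpa(specs, slide = TRUE)
  for (i in seq_along(specs)) {
    x <- specs[[i]]$coords
    x <- calomorph:::center_scale(x)
    x <- x %*% calomorph:::procrustes_rotation(x, sp$consensus)
    d_unslid <- sum((x - sp$consensus)^2)
    slid <- calomorph:::slide_semilandmarks(x, sp$consensus, c(4L, 9L))
    expect_lte(sum((slid - sp$consensus)^2), d_unslid + 1e-14)
    expect_lte(sum((sp$aligned[[i]] - sp$consensus)^2), d_unslid + 1e-10)
  }
})

test_that("shape variables have dimension 2k-4 and split affine from warps", {
  set.seed(17)
  specs <- noisy_configs(reference_config(), 10, sd = 0.03)
  sp <- gpa(specs, slide = FALSE)
  sv <- shape_variables(sp)
  expect_identical(dim(sv$scores), c(10L, 20L))   # 2*12 - 4
  expect_equal(crossprod(sv$basis), diag(20), tolerance = 1e-10)

  # a pure affine (uniform) deformation of the consensus loads only on
  # the two uniform columns
  A <- matrix(c(1, 0.08, 0.05, 1), 2, 2)
  aff <- sp$consensus %*% A
  sp_aff <- sp
  sp_aff$aligned <- list(calomorph:::center_scale(aff))
  sv_aff <- shape_variables(sp_aff)
  expect_lt(max(abs(sv_aff$scores[1, 1:18])), 1e-8)
  expect_gt(max(abs(sv_aff$scores[1, 19:20])), 1e-4)

  # round trip: scores x basis reproduces the tangent-projected
  # residuals exactly
  rec <- sv$scores %*% t(sv$basis)
  cons_vec <- c(sp$consensus[, 1], sp$consensus[, 2])
  for (i in c(1, 5, 10)) {
    expect_equal(rec[i, ], sv$tangent[i, ] - cons_vec,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # with near-infinitesimal variation the aligned coordinates themselves
  # are recovered (projection error is second order)
  tiny <- noisy_configs(reference_config(), 6, sd = 5e-5)
  spt <- gpa(tiny, slide = FALSE)
  svt <- shape_variables(spt)
  rect <- svt$scores %*% t(svt$basis)
  ct <- c(spt$consensus[, 1], spt$consensus[, 2])
  for (i in 1:6) {
    ali <- c(spt$aligned[[i]][, 1], spt$aligned[[i]][, 2]) - ct
    expect_lt(max(abs(rect[i, ] - ali)), 1e-8)
  }
  # total variance carried by the scores equals tangent-space variance
  Vt <- sv$tangent - matrix(c(sp$consensus), 10, 24, byrow = TRUE)
  expect_equal(sum(apply(sv$scores, 2, var)), sum(apply(Vt, 2, var)),
               tolerance = 1e-8)
})

test_that("interpolating TPS maps landmarks exactly and matches a direct solve", {
  set.seed(19)
  cons <- reference_config()
  targ <- cons + matrix(rnorm(24, 0, 0.1), 12, 2)
  g <- tps_grid(cons, targ, grid_density = 8)
  mapped <- calomorph:::tps_apply(cons, cons, g$coefficients$W,
                                  g$coefficients$A)
  expect_lt(max(abs(mapped - targ)), 1e-10)

  # independent dense solve of the bordered kernel system
  d2 <- as.matrix(dist(cons))^2
  K <- d2 * log(pmax(d2, 1e-300)); diag(K) <- 0
  Q <- cbind(1, cons)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  sol <- solve(L, rbind(targ, matrix(0, 3, 2)))
  expect_equal(g$coefficients$W, sol[1:12, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(g$coefficients$A, sol[13:15, ], tolerance = 1e-9,
               ignore_attr = TRUE)

  # identity deformation: zero bending energy, grid unmoved
  gid <- tps_grid(cons, cons, grid_density = 6)
  expect_equal(gid$bending_energy, 0, tolerance = 1e-10)
  expect_equal(gid$mapped_grid, gid$source_grid, tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(tps_grid(cbind(1:5, 2 * (1:5)), cbind(1:5, 1:5)),
               "singular")
})

test_that("shape scores recover a known allometric axis", {
  set.seed(23)
  cons <- calomorph:::center_scale(reference_config())
  beta <- rnorm(24); beta <- beta / sqrt(sum(beta^2)) * 0.02
  n <- 200
  x <- rnorm(n)
  specs <- lapply(seq_len(n), function(i) {
    noise <- rnorm(24, 0, 0.0015)
    landmark_set(cons + matrix(x[i] * beta + noise, 12, 2))
  })
  sp <- gpa(specs, slide = FALSE)
  sc <- shape_scores(sp, x)
  expect_gt(abs(cor(sc, x)), 0.99)

  # affine invariance under covariate rescaling
  sc2 <- shape_scores(sp, 5 * x + 3)
  expect_gt(abs(cor(sc, sc2)), 1 - 1e-10)

  # identical specimens give identical scores
  same <- gpa(lapply(1:5, function(i) landmark_set(cons)), slide = FALSE)
  expect_equal(var(shape_scores(same, rnorm(5))), 0, tolerance = 1e-20)
  expect_error(shape_scores(sp, rep(1, n)), "constant")
})
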