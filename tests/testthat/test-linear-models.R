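test_that("species means aggregate specimen tables correctly", {
  same <- data.frame(taxon = "a", wing = "fore", rsm = rep(0.55, 10),
                     log_centroid_size = rep(4, 10))
  expect_equal(species_means(same)$rsm_mean, 0.55)
  two <- data.frame(taxon = "a", wing = "fore", rsm = c(0.5, 0.7),
                    log_centroid_size = c(1, 3))
  m <- species_means(two)
  expect_equal(m$rsm_mean, 0.6)
  expect_equal(m$log_centroid_size_mean, 2)
  expect_equal(m$n_specimens, 2L)

  # 37 taxa x 10 specimens against a direct-summation oracle
  set.seed(31)
  big <- data.frame(taxon = rep(sprintf("t%02d", 1:37), each = 10),
                    wing = "hind", rsm = runif(370, 0.4, 0.7),
                    log_centroid_size = rnorm(370, 4, 0.2))
  mm <- species_means(big)
  expect_equal(nrow(mm), 37)
  for (tx in c("t01", "t20", "t37")) {
    rows <- big$rsm[big$taxon == tx]
    expect_equal(mm$rsm_mean[mm$taxon == tx], sum(rows) / length(rows))
  }
})

test_that("polynomial regression reports OLS fits with the right df", {
  set.seed(37)
  x <- rnorm(37); y <- 1 + 2 * x - 0.5 * x^2
  f2 <- suppressWarnings(polynomial_regression(y, x, 2))  # exact fit
  expect_equal(f2$r_squared, 1)
  expect_equal(f2$df, c(2, 34))
  f1 <- polynomial_regression(y, x, 1)
  expect_equal(f1$df, c(1, 35))

  # coefficients equal the normal-equation solution
  y2 <- y + rnorm(37, 0, 0.3)
  f <- polynomial_regression(y2, x, 2)
  X <- cbind(1, x, x^2)
  expect_equal(unname(f$coefficients),
               unname(drop(solve(crossprod(X), crossprod(X, y2)))),
               tolerance = 1e-10)
  expect_error(polynomial_regression(y[1:3], x[1:3], 2), "n >")
})

test_that("Wilks' lambda equals the determinant-ratio oracle", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 30; p <- 3
    Y <- matrix(rnorm(n * p), n, p)
    gr <- factor(sample(letters[1:3], n, replace = TRUE))
    cv <- rnorm(n)
    fit <- mancova_wilks(Y, gr, cv)
    X_full <- cbind(1, model.matrix(~gr)[, -1], cv)
    hatm <- function(X) X %*% solve(crossprod(X), t(X))
    E <- crossprod(Y - hatm(X_full) %*% Y)
    X_red <- cbind(1, model.matrix(~gr)[, -1])
    Er <- crossprod(Y - hatm(X_red) %*% Y)
    expect_equal(fit$table["covariate", "wilks_lambda"],
                 det(E) / det(Er), tolerance = 1e-10)
  }
})

test_that("univariate MANCOVA reduces exactly to the ANCOVA F test", {
  set.seed(43)
  n <- 25
  y <- rnorm(n); gr <- factor(rep(1:2, length.out = n)); cv <- rnorm(n)
  m <- mancova_wilks(matrix(y, ncol = 1), gr, cv)
  a <- ancova(y, gr, cv)
  expect_equal(m$table["group", "F"], a$table["group", "F"],
               tolerance = 1e-10)
  expect_equal(m$table["covariate", "F"], a$table["covariate", "F"],
               tolerance = 1e-10)
  expect_equal(m$table["group", "df2"], a$table["Error", "df"])
})

test_that("MANCOVA degrees of freedom match the two-wing species design", {
  set.seed(47)
  n <- 74; p <- 20
  Y <- matrix(rnorm(n * p), n, p)
  wing <- factor(rep(c("fore", "hind"), each = 37))
  rsm <- rnorm(n)
  fit <- mancova_wilks(Y, wing, rsm)
  expect_equal(fit$table["covariate", "df1"], 20)
  expect_equal(fit$table["covariate", "df2"], 52)
  expect_error(mancova_wilks(matrix(rnorm(10 * 9), 10, 9),
                             factor(rep(1:2, 5)), rnorm(10)),
               "reduce the response")
})

test_that("ANCOVA has the Odonata-layout df and behaves at the null", {
  set.seed(53)
  n <- 108
  grp <- factor(rep(c("calo", "non-calo", "dragon"), c(27, 27, 54)))
  bl <- rnorm(n)
  y <- rnorm(n)
  a <- ancova(y, grp, bl)
  expect_equal(a$table["group", "df"], 2)
  expect_equal(a$table["Error", "df"], 104)

  # under a true null the group F rejects at ~alpha
  rej <- vapply(1:400, function(i) {
    yy <- rnorm(30)
    aa <- ancova(yy, factor(rep(1:3, 10)), rnorm(30))
    aa$table["group", "p_value"] < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("coloration GLM reproduces the published table layout", {
  set.seed(59)
  n <- 37
  grp <- factor(sample(1:6, n, replace = TRUE))
  while (nlevels(droplevels(grp)) < 6) {
    grp <- factor(sample(1:6, n, replace = TRUE))
  }
  cs <- rnorm(n, 4, 0.2)
  rsm <- 0.56 - 0.05 * cs + rnorm(n, 0, 0.01)
  g <- glm_coloration(rsm, grp, cs)
  expect_equal(g$table["Error", "df"], 29)   # 37 - 5 - 2 - 1
  expect_equal(rownames(g$table),
               c("coloration_group", "log_cs", "log_cs_sq", "Error"))

  # sums of squares add to the total SS for balanced orthogonal designs
  gb <- factor(rep(1:2, each = 8))
  xb <- rep(c(-1, 1), 8)
  yb <- rnorm(16)
  fit <- stats::lm(yb ~ gb + xb)
  an <- anova(fit)
  expect_equal(sum(an$`Sum Sq`), sum((yb - mean(yb))^2), tolerance = 1e-10)

  # group p-value roughly uniform under the null
  pv <- vapply(1:300, function(i) {
    y0 <- rnorm(37)
    glm_coloration(y0, grp, cs)$table["coloration_group", "p_value"]
  }, 0)
  expect_gt(mean(pv < 0.05), 0.01)
  expect_lt(mean(pv < 0.05), 0.10)
})

test_that("non-allometric residuals are exact quadratic-regression residuals", {
  set.seed(61)
  cs <- rnorm(30, 4, 0.3)
  rsm <- 0.6 - 0.02 * cs + 0.005 * cs^2
  expect_equal(max(abs(nonallometric_residuals(rsm, cs))), 0,
               tolerance = 1e-10)
  y <- rsm + rnorm(30, 0, 0.01)
  r <- nonallometric_residuals(y, cs)
  expect_equal(sum(r), 0, tolerance = 1e-10)
  expect_equal(sum(r * cs), 0, tolerance = 1e-10)
  expect_equal(sum(r * cs^2), 0, tolerance = 1e-9)
  X <- cbind(1, cs, cs^2)
  expect_equal(unname(r), drop(y - X %*% solve(crossprod(X), crossprod(X, y))),
               tolerance = 1e-10)
})
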