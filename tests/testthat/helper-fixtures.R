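# Canonical outlines with closed-form moment radii -------------------------

rect_outline <- function(len = 1, height = 0.2) {
  wing_outline(rbind(c(0, 0), c(len, 0), c(len, height), c(0, height)),
               base = c(0, height / 2), apex = c(len, height / 2))
}

# full chord at the base tapering linearly to the apex: c-hat = 2(1 - r)
root_triangle_outline <- function() {
  wing_outline(rbind(c(0, -0.5), c(1, 0), c(0, 0.5)),
               base = c(0, 0), apex = c(1, 0))
}

# chord grows linearly toward the apex: c-hat = 2r
tip_triangle_outline <- function() {
  wing_outline(rbind(c(0, 0), c(1, -0.5), c(1, 0.5)),
               base = c(0, 0), apex = c(1, 0))
}

rotate_outline <- function(outline, theta, shift = c(0, 0)) {
  Q <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  tx <- function(p) drop(Q %*% p) + shift
  wing_outline(t(apply(outline$vertices, 1, tx)),
               base = tx(outline$base), apex = tx(outline$apex))
}

# a well-conditioned 12-landmark reference configuration
reference_config <- function() {
  set.seed(420)
  cbind(runif(12, 0, 3), runif(12, 0, 1))
}

noisy_configs <- function(base, n, sd = 0.02, semis = integer(0)) {
  lapply(seq_len(n), function(i) {
    landmark_set(base + matrix(rnorm(length(base), 0, sd), nrow(base), 2),
                 semilandmarks = semis)
  })
}

# brute-force full-Procrustes distance by rotation grid search
grid_procrustes_distance <- function(A, B, step = 0.001) {
  A <- sweep(A, 2, colMeans(A)); A <- A / sqrt(sum(A^2))
  B <- sweep(B, 2, colMeans(B)); B <- B / sqrt(sum(B^2))
  th <- seq(0, 2 * pi, by = step)
  d <- vapply(th, function(t) {
    Q <- rbind(c(cos(t), -sin(t)), c(sin(t), cos(t)))
    sum((A %*% Q - B)^2)
  }, 0)
  sqrt(min(d))
}

# GLS slope of y on x (with intercept) under Brownian covariance
gls_slope <- function(tree, x, y) {
  V <- ape::vcv(tree)
  ord <- rownames(V)
  X <- cbind(1, x[ord])
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y[ord]))[2]
}
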