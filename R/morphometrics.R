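#' Construct a landmark set
#'
#' @param coords k x 2 numeric matrix of landmark coordinates in physical
#'   units (k >= 3, no two landmarks coincident).
#' @param semilandmarks Integer indices of semilandmarks (points without
#'   point-to-point homology, allowed to slide along the outline tangent
#'   during superimposition).  Must be a proper subset of `1:k`.
#' @param specimen_id,taxon_id,wing Optional labels.
#' @return A `landmark_set` object.
#' @export
landmark_set <- function(coords, semilandmarks = integer(0),
                         specimen_id = NA_character_,
                         taxon_id = NA_character_, wing = NA_character_) {
  coords <- as.matrix(coords)
  k <- nrow(coords)
  stopifnot(ncol(coords) == 2, k >= 3)
  if (anyDuplicated(coords) > 0) stop("coincident landmarks")
  semilandmarks <- as.integer(semilandmarks)
  if (length(semilandmarks)) {
    stopifnot(all(semilandmarks >= 1L & semilandmarks <= k),
              !anyDuplicated(semilandmarks), length(semilandmarks) < k)
  }
  structure(list(coords = coords, semilandmarks = sort(semilandmarks),
                 specimen_id = specimen_id, taxon_id = taxon_id,
                 wing = wing),
            class = "landmark_set")
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks to
#' their centroid — the standard geometric-morphometric size measure, used
#' log-transformed as the size proxy throughout the pipeline (centroid
#' size is highly correlated with body size in calopterygids).
#'
#' @param coords k x 2 matrix (k >= 3) or a `landmark_set`.
#' @return Positive scalar.
#' @export
centroid_size <- function(coords) {
  if (inherits(coords, "landmark_set")) coords <- coords$coords
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 3, ncol(coords) == 2)
  cs <- sqrt(sum(sweep(coords, 2, colMeans(coords))^2))
  if (cs == 0) stop("degenerate configuration: all landmarks coincident")
  cs
}

# Optimal rotation (no reflection unless allowed) aligning X onto Y, both
# centered.  Returns the 2x2 rotation matrix Q minimising ||X Q - Y||.
procrustes_rotation <- function(X, Y, allow_reflection = FALSE) {
  M <- crossprod(X, Y)
  sv <- svd(M)
  Q <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(Q) < 0) {
    u <- sv$u
    u[, 2] <- -u[, 2]
    Q <- u %*% t(sv$v)
  }
  Q
}

center_scale <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  X / sqrt(sum(X^2))
}

# slide semilandmarks of aligned configuration X along discrete tangents
# toward the consensus (minimised Procrustes distance criterion)
slide_semilandmarks <- function(X, consensus, semis) {
  k <- nrow(X)
  for (i in semis) {
    nb <- c(if (i > 1L) i - 1L, if (i < k) i + 1L)
    tg <- X[nb[length(nb)], ] - X[nb[1L], ]
    nt <- sqrt(sum(tg^2))
    if (nt == 0) next
    tg <- tg / nt
    lambda <- sum(tg * (consensus[i, ] - X[i, ]))
    X[i, ] <- X[i, ] + lambda * tg
  }
  X
}

#' Generalized Procrustes Analysis with optional sliding semilandmarks
#'
#' Iterative superimposition: every configuration is translated to the
#' origin, scaled to unit centroid size, and rotated to minimise its
#' summed squared deviation from the current consensus; the consensus is
#' the mean of the aligned configurations, renormalised to unit centroid
#' size.  Iteration stops when the root-mean-square change of the
#' consensus falls below `tol`.
#'
#' With `slide = TRUE`, after each superimposition pass every semilandmark
#' is displaced along its discrete tangent direction (the chord between
#' its neighbouring landmarks; end points use the single adjacent chord)
#' by the projection of its residual from the consensus — the sliding step
#' that minimises Procrustes distance to the consensus.  Slid
#' configurations are re-normalised and re-aligned, alternating until the
#' consensus stabilises.
#'
#' Reflections are not allowed by default (wings of one body side);
#' `allow_reflection = TRUE` enables them for mixed-side data.
#'
#' @param specimens List of [landmark_set()] objects (or k x 2 matrices),
#'   all with the same k and the same semilandmark set.
#' @param slide Slide semilandmarks (default `TRUE` when any are flagged).
#' @param tol Convergence tolerance on consensus RMS change.
#' @param max_iter Maximum GPA iterations (default 500: sliding semilandmarks converge linearly and need a few hundred passes at tight tolerance).
#' @param allow_reflection Allow improper rotations.
#' @return A `shape_space` object: `consensus` (k x 2, unit centroid size,
#'   centred), `aligned` (list of k x 2 matrices), `centroid_sizes`,
#'   `semilandmarks`, `iterations`, `labels` (data.frame of specimen
#'   metadata).
#' @export
gpa <- function(specimens, slide = NULL, tol = 1e-10, max_iter = 500,
                allow_reflection = FALSE) {
  stopifnot(length(specimens) >= 1)
  specimens <- lapply(specimens, function(s) {
    if (inherits(s, "landmark_set")) s else landmark_set(s)
  })
  k <- nrow(specimens[[1]]$coords)
  semis <- specimens[[1]]$semilandmarks
  for (s in specimens) {
    if (nrow(s$coords) != k) stop("mismatched landmark count across specimens")
    if (!identical(s$semilandmarks, semis)) {
      stop("mismatched semilandmark sets across specimens")
    }
  }
  if (is.null(slide)) slide <- length(semis) > 0
  n <- length(specimens)
  cs <- vapply(specimens, function(s) centroid_size(s$coords), 0)
  orig <- lapply(specimens, function(s) center_scale(s$coords))
  aligned <- orig

  consensus <- center_scale(orig[[1]])
  iterations <- 0L
  ss_trace <- numeric(0)
  repeat {
    iterations <- iterations + 1L
    # each pass starts from the original configurations, so the slid
    # state is a deterministic function of the current consensus (no
    # accumulation of sliding displacements across iterations)
    aligned <- lapply(orig, function(X) {
      X <- X %*% procrustes_rotation(X, consensus, allow_reflection)
      if (slide && length(semis)) {
        X <- slide_semilandmarks(X, consensus, semis)
        X <- center_scale(X)
        X <- X %*% procrustes_rotation(X, consensus, allow_reflection)
      }
      X
    })
    mean_config <- Reduce(`+`, aligned) / n
    new_consensus <- center_scale(mean_config)
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    # Gower objective: summed squared deviation from the (unnormalised)
    # mean — provably non-increasing under rotate-then-average iterations
    ss_trace <- c(ss_trace,
                  sum(vapply(aligned,
                             function(X) sum((X - mean_config)^2), 0)))
    if (delta < tol) break
    if (iterations >= max_iter) {
      stop("GPA did not converge in ", max_iter,
           " iterations (last consensus RMS change ",
           format(delta, digits = 3), ")")
    }
  }
  # final alignment to the converged consensus
  aligned <- lapply(aligned, function(X) {
    X %*% procrustes_rotation(X, consensus, allow_reflection)
  })
  labels <- data.frame(
    specimen_id = vapply(specimens, function(s) s$specimen_id, ""),
    taxon_id = vapply(specimens, function(s) s$taxon_id, ""),
    wing = vapply(specimens, function(s) s$wing, ""),
    stringsAsFactors = FALSE)
  structure(list(consensus = consensus, aligned = aligned,
                 centroid_sizes = cs, semilandmarks = semis,
                 iterations = iterations, ss_trace = ss_trace,
                 labels = labels),
            class = "shape_space")
}

#' Full Procrustes distance between two configurations
#'
#' Both configurations are centred and scaled to unit centroid size; the
#' distance is the minimum root summed squared difference over rotations.
#'
#' @param A,B k x 2 matrices.
#' @param allow_reflection Allow improper rotations.
#' @export
procrustes_distance <- function(A, B, allow_reflection = FALSE) {
  A <- center_scale(as.matrix(A)); B <- center_scale(as.matrix(B))
  Q <- procrustes_rotation(A, B, allow_reflection)
  sqrt(sum((A %*% Q - B)^2))
}

# thin-plate spline kernel U(r) = r^2 log r^2, with U(0) = 0
tps_kernel <- function(d2) {
  out <- d2 * log(pmax(d2, .Machine$double.xmin))
  out[d2 == 0] <- 0
  out
}

# bending-energy matrix of a reference configuration: the upper-left k x k
# block of the inverse of the bordered TPS system [[K, Q], [Q', 0]]
bending_energy_matrix <- function(ref) {
  k <- nrow(ref)
  d2 <- as.matrix(stats::dist(ref))^2
  K <- tps_kernel(d2)
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Li <- solve(L)
  Be <- Li[1:k, 1:k]
  (Be + t(Be)) / 2
}

#' Partial-warp and uniform-component shape variables
#'
#' Computes the standard 2k-4 shape variables of a 2D landmark data set:
#' 2k-6 partial-warp scores (projections of the tangent-space residuals on
#' the non-zero eigenvectors of the consensus bending-energy matrix,
#' ordered by decreasing bending energy) followed by the 2-column uniform
#' (affine) component, constructed as the orthonormal basis of affine
#' deformations of the consensus orthogonal to the similarity
#' transformations.  A purely affine deformation therefore loads only on
#' the last two columns.
#'
#' Residuals are orthogonally projected onto the tangent space at the
#' consensus (removing the residual components along the consensus scaling
#' and rotation directions) before scoring, so the variable matrix carries
#' exactly the tangent-space variance.
#'
#' @param space A `shape_space` from [gpa()].
#' @return A list: `scores` (n x (2k-4) matrix), `basis` (2k x (2k-4)
#'   orthonormal matrix, coordinates stacked x then y), `bending_energies`
#'   (length 2k-4; 0 for the uniform columns), `tangent` (n x 2k matrix of
#'   tangent-projected aligned coordinates).
#' @export
shape_variables <- function(space) {
  stopifnot(inherits(space, "shape_space"))
  ref <- space$consensus
  k <- nrow(ref)
  if (k < 4) stop("at least 4 landmarks needed for shape variables")
  Be <- bending_energy_matrix(ref)
  ee <- eigen(Be, symmetric = TRUE)
  pos <- ee$values > max(ee$values) * 1e-9
  E <- ee$vectors[, pos, drop = FALSE]        # k x (k-3) principal warps
  lam <- ee$values[pos]                       # decreasing
  # partial-warp basis in stacked (x, y) coordinates: each principal warp
  # contributes an x-displacement and a y-displacement basis vector
  zero <- matrix(0, k, ncol(E))
  pw_basis <- cbind(rbind(E, zero), rbind(zero, E))  # 2k x (2k-6)
  ord <- order(rep(lam, 2), decreasing = TRUE)
  pw_basis <- pw_basis[, ord, drop = FALSE]
  pw_energy <- rep(lam, 2)[ord]

  # uniform basis: affine deformations of the consensus, minus similarity
  x <- ref[, 1]; y <- ref[, 2]
  aff <- cbind(c(x, 0 * x), c(y, 0 * y), c(0 * x, x), c(0 * y, y))
  sim <- cbind(c(x, y), c(-y, x))   # scaling and rotation directions
  P <- diag(2 * k) - sim %*% solve(crossprod(sim), t(sim))
  U <- P %*% aff
  qrU <- qr(U)
  U <- qr.Q(qrU)[, seq_len(qrU$rank), drop = FALSE]
  if (ncol(U) != 2) stop("uniform component is not two-dimensional ",
                         "(degenerate consensus)")

  basis <- cbind(pw_basis, U)
  # tangent-space projection: remove residual components along the
  # similarity directions at the consensus (translations are already gone)
  n <- length(space$aligned)
  cons_vec <- c(ref[, 1], ref[, 2])
  V <- t(vapply(space$aligned,
                function(X) c(X[, 1], X[, 2]) - cons_vec,
                numeric(2 * k)))
  Psim <- diag(2 * k) - sim %*% solve(crossprod(sim), t(sim))
  Vt <- V %*% Psim
  scores <- Vt %*% basis
  colnames(scores) <- c(paste0("PW", seq_len(ncol(pw_basis))), "U1", "U2")
  list(scores = scores, basis = basis,
       bending_energies = c(pw_energy, 0, 0),
       tangent = sweep(Vt, 2, -cons_vec))
}

#' Thin-plate spline deformation grid
#'
#' Fits the interpolating thin-plate spline (kernel U(r) = r^2 log r^2)
#' mapping a reference configuration onto a target, and evaluates it on a
#' square grid spanning the reference bounding box (with a margin).  Used
#' to visualise shape change as a deformation of the consensus, in the
#' classical transformation-grid style.
#'
#' @param consensus,target k x 2 matrices (aligned, same k).
#' @param grid_density Grid points per side (default 24).
#' @param margin Fractional bounding-box margin (default 0.1).
#' @return A `deformation_grid` object: `source_grid` and `mapped_grid`
#'   (grid_density^2 x 2), `coefficients` (list `W` k x 2 warp weights,
#'   `A` 3 x 2 affine part), `bending_energy` (scalar, the non-affine
#'   energy of the map), plus the inputs.
#' @export
tps_grid <- function(consensus, target, grid_density = 24, margin = 0.1) {
  consensus <- as.matrix(consensus); target <- as.matrix(target)
  k <- nrow(consensus)
  stopifnot(nrow(target) == k, ncol(consensus) == 2, ncol(target) == 2,
            grid_density >= 2)
  d2 <- as.matrix(stats::dist(consensus))^2
  K <- tps_kernel(d2)
  Q <- cbind(1, consensus)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  rhs <- rbind(target, matrix(0, 3, 2))
  sol <- tryCatch(solve(L, rhs), error = function(e) {
    stop("singular thin-plate spline system (collinear or coincident ",
         "landmarks): ", conditionMessage(e))
  })
  W <- sol[1:k, , drop = FALSE]
  A <- sol[(k + 1):(k + 3), , drop = FALSE]
  rngx <- range(consensus[, 1]); rngy <- range(consensus[, 2])
  mx <- margin * diff(rngx); my <- margin * diff(rngy)
  gx <- seq(rngx[1] - mx, rngx[2] + mx, length.out = grid_density)
  gy <- seq(rngy[1] - my, rngy[2] + my, length.out = grid_density)
  src <- as.matrix(expand.grid(x = gx, y = gy))
  mapped <- tps_apply(src, consensus, W, A)
  be <- sum(diag(t(W) %*% K %*% W))
  structure(list(source_grid = src, mapped_grid = mapped,
                 coefficients = list(W = W, A = A),
                 bending_energy = be,
                 consensus = consensus, target = target),
            class = "deformation_grid")
}

# evaluate a fitted TPS at arbitrary points
tps_apply <- function(pts, centers, W, A) {
  pts <- as.matrix(pts)
  d2 <- outer(pts[, 1], centers[, 1], `-`)^2 +
        outer(pts[, 2], centers[, 2], `-`)^2
  U <- tps_kernel(d2)
  cbind(1, pts) %*% A + U %*% W
}

#' Allometric shape scores from a regression of shape on a covariate
#'
#' The Drake-Klingenberg shape score: each tangent-space shape coordinate
#' is regressed on the covariate; every specimen's (centred) shape is then
#' projected onto the unit regression vector.  The score summarises all
#' landmark information in one value per specimen, including the residual
#' variation lying along the regression direction of shape space.
#'
#' @param space A `shape_space` from [gpa()].
#' @param covariate Numeric vector, one value per specimen, non-constant.
#' @return Numeric vector of scores (one per specimen).
#' @export
shape_scores <- function(space, covariate) {
  stopifnot(inherits(space, "shape_space"))
  n <- length(space$aligned)
  stopifnot(length(covariate) == n)
  if (stats::var(covariate) == 0) {
    stop("degenerate regression: covariate is constant")
  }
  Y <- t(vapply(space$aligned, function(X) c(X[, 1], X[, 2]),
                numeric(2 * nrow(space$consensus))))
  Yc <- sweep(Y, 2, colMeans(Y))
  xc <- covariate - mean(covariate)
  beta <- drop(crossprod(Yc, xc)) / sum(xc^2)
  nb <- sqrt(sum(beta^2))
  if (nb == 0) return(rep(0, n))
  drop(Yc %*% (beta / nb))
}
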