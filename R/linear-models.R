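#' Species means of specimen-level measurements
#'
#' Species are the level of replication for all comparative analyses:
#' per-specimen RSM and log centroid size are averaged within each
#' taxon x wing cell.
#'
#' @param specimen_table data.frame with columns `taxon`, `wing`, `rsm`,
#'   `log_centroid_size`, and optionally `coloration_group`.
#' @return data.frame with one row per taxon x wing: `taxon`, `wing`,
#'   `rsm_mean`, `log_centroid_size_mean`, `n_specimens` (and
#'   `coloration_group` if supplied).
#' @export
species_means <- function(specimen_table) {
  df <- specimen_table
  stopifnot(all(c("taxon", "wing", "rsm", "log_centroid_size") %in% names(df)))
  key <- interaction(df$taxon, df$wing, drop = TRUE)
  agg <- function(v) tapply(v, key, mean)
  out <- data.frame(
    taxon = tapply(df$taxon, key, `[`, 1),
    wing = tapply(df$wing, key, `[`, 1),
    rsm_mean = as.numeric(agg(df$rsm)),
    log_centroid_size_mean = as.numeric(agg(df$log_centroid_size)),
    n_specimens = as.integer(tapply(df$rsm, key, length)),
    stringsAsFactors = FALSE)
  if (!is.null(df$coloration_group)) {
    grp <- tapply(df$coloration_group, key, `[`, 1)
    out$coloration_group <- as.integer(grp)
  }
  rownames(out) <- NULL
  out[order(out$wing, out$taxon), ]
}

new_fit_result <- function(kind, table, stats = list()) {
  structure(c(list(kind = kind, table = table), stats),
            class = "calomorph_fit")
}

#' @export
print.calomorph_fit <- function(x, ...) {
  cat(x$kind, "\n")
  if (!is.null(x$r_squared)) {
    cat(sprintf("  R^2 = %.3f, F_%d,%d = %.3f, P = %.4g\n",
                x$r_squared, x$df[1], x$df[2], x$F, x$p_value))
  }
  if (!is.null(x$table)) print(x$table, digits = 4)
  invisible(x)
}

#' Linear or quadratic regression of one variable on another
#'
#' Ordinary least squares of `y` on powers of `x` up to `degree`; the
#' standard first look at the allometry of the RSM on log wing centroid
#' size.  For n species the overall F carries (degree, n - degree - 1)
#' degrees of freedom.
#'
#' @param y,x Numeric vectors of equal length.
#' @param degree 1 (linear) or 2 (quadratic).
#' @return A `calomorph_fit` with `coefficients`, `r_squared`, `F`, `df`,
#'   `p_value`, `residuals`, `table` (per-coefficient tests), and the
#'   underlying `lm` fit as `model`.
#' @export
polynomial_regression <- function(y, x, degree = 1) {
  stopifnot(degree %in% c(1, 2), length(y) == length(x))
  n <- length(y)
  if (n <= degree + 1) stop("need n > degree + 1 observations")
  dat <- data.frame(y = y, x = x)
  fml <- if (degree == 1) y ~ x else y ~ x + I(x^2)
  fit <- stats::lm(fml, data = dat)
  if (fit$rank < degree + 1) stop("rank-deficient (collinear) design")
  sm <- summary(fit)
  fstat <- sm$fstatistic
  new_fit_result(
    paste0(c("linear", "quadratic")[degree], " regression"),
    as.data.frame(sm$coefficients),
    list(coefficients = stats::coef(fit),
         r_squared = sm$r.squared,
         F = unname(fstat[1]),
         df = unname(c(fstat[2], fstat[3])),
         p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                    lower.tail = FALSE)),
         residuals = stats::residuals(fit),
         model = fit))
}

# Wilks' lambda and Rao's F approximation for one model term.
# E: error SSCP of the full model; H: extra SSCP when the term is dropped;
# q: term df; df_e: error df of the full model.
wilks_rao_f <- function(E, H, q, df_e) {
  p <- ncol(E)
  lambda <- det(E) / det(E + H)
  s2 <- (p^2 * q^2 - 4) / (p^2 + q^2 - 5)
  s <- if (is.finite(s2) && s2 > 0) sqrt(s2) else 1
  m <- df_e - (p - q + 1) / 2
  df1 <- p * q
  df2 <- m * s - p * q / 2 + 1
  L <- lambda^(1 / s)
  Fv <- (1 - L) / L * df2 / df1
  c(lambda = lambda, F = Fv, df1 = df1, df2 = df2,
    p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

#' MANCOVA with Wilks' lambda
#'
#' Multivariate analysis of covariance of a response matrix (typically the
#' partial-warp + uniform shape variables) on a fixed factor plus a
#' continuous covariate, without their interaction.  Each term is tested by
#' Wilks' lambda with the term's hypothesis SSCP computed partially (the
#' increase in error SSCP when that term alone is dropped from the full
#' model), converted to an F statistic by Rao's approximation.
#'
#' @param Y n x p numeric response matrix (p < error df).
#' @param group Factor with >= 2 levels.
#' @param covariate Numeric vector, or `NULL` for a one-way MANOVA.
#' @return A `calomorph_fit` whose `table` has one row per term with
#'   columns `wilks_lambda`, `F`, `df1`, `df2`, `p_value`.
#' @export
mancova_wilks <- function(Y, group, covariate = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  group <- droplevels(as.factor(group))
  stopifnot(nlevels(group) >= 2, length(group) == n)
  terms <- list(group = stats::model.matrix(~group)[, -1, drop = FALSE])
  if (!is.null(covariate)) {
    stopifnot(length(covariate) == n)
    terms$covariate <- matrix(covariate, ncol = 1)
  }
  X_full <- cbind(`(Intercept)` = 1, do.call(cbind, terms))
  rank_full <- qr(X_full)$rank
  df_e <- n - rank_full
  if (ncol(Y) >= df_e) {
    stop("singular within-group covariance: p = ", ncol(Y),
         " responses but only ", df_e,
         " error df; reduce the response dimension")
  }
  sscp_resid <- function(X) {
    Q <- qr.Q(qr(X))
    R <- Y - Q %*% crossprod(Q, Y)
    crossprod(R)
  }
  E <- sscp_resid(X_full)
  rows <- lapply(names(terms), function(nm) {
    X_red <- cbind(1, do.call(cbind, terms[setdiff(names(terms), nm)]))
    H <- sscp_resid(X_red) - E
    q <- rank_full - qr(X_red)$rank
    wilks_rao_f(E, H, q, df_e)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c("wilks_lambda", "F", "df1", "df2", "p_value")
  rownames(tab) <- names(terms)
  new_fit_result("MANCOVA (Wilks' lambda, Rao F)", tab,
                 list(error_df = df_e, n = n, p = ncol(Y)))
}

#' ANCOVA of a response on a group factor plus a covariate
#'
#' Group and covariate F tests, each adjusted for the other (partial sums
#' of squares), on the layout used for comparing the RSM among Odonata
#' groups with body length as the covariate.
#'
#' @param y Numeric response.
#' @param group Factor with >= 2 levels.
#' @param covariate Numeric vector.
#' @return A `calomorph_fit`; `table` has rows `group`, `covariate`,
#'   `Error` with `df`, `SS`, `F`, `p_value`.
#' @export
ancova <- function(y, group, covariate) {
  group <- droplevels(as.factor(group))
  stopifnot(nlevels(group) >= 2,
            length(y) == length(group), length(y) == length(covariate))
  fit <- stats::lm(y ~ group + covariate)
  dr <- stats::drop1(fit, scope = ~ group + covariate, test = "F")
  err_df <- fit$df.residual
  err_ss <- sum(stats::residuals(fit)^2)
  tab <- data.frame(
    df = c(dr$Df[-1], err_df),
    SS = c(dr$`Sum of Sq`[-1], err_ss),
    F = c(dr$`F value`[-1], NA),
    p_value = c(dr$`Pr(>F)`[-1], NA),
    row.names = c("group", "covariate", "Error"))
  new_fit_result("ANCOVA (partial SS)", tab, list(model = fit))
}

#' General linear model of the RSM on coloration group and size
#'
#' RSM as response, wing coloration group as a fixed factor, log wing
#' centroid size and its square as covariates, no interactions (the
#' published protocol removes non-significant interactions; this fits the
#' main-effects model those removals leave).  Each term's sum of squares
#' is partial — adjusted for every other term — reproducing the
#' SPSS-style Type III table layout.  Error df = n - (levels - 1) - 2 - 1.
#'
#' @param rsm Numeric response (species-mean RSM).
#' @param coloration_group Factor (or integer 1-6).
#' @param log_cs Numeric log centroid size (species mean).
#' @return A `calomorph_fit`; `table` rows `coloration_group`, `log_cs`,
#'   `log_cs_sq`, `Error`.
#' @export
glm_coloration <- function(rsm, coloration_group, log_cs) {
  g <- droplevels(as.factor(coloration_group))
  stopifnot(length(rsm) == length(g), length(rsm) == length(log_cs))
  dat <- data.frame(rsm = rsm, g = g, cs = log_cs)
  fit <- stats::lm(rsm ~ g + cs + I(cs^2), data = dat)
  dr <- stats::drop1(fit, scope = ~ g + cs + I(cs^2), test = "F")
  err_df <- fit$df.residual
  err_ss <- sum(stats::residuals(fit)^2)
  tab <- data.frame(
    df = c(dr$Df[-1], err_df),
    SS = c(dr$`Sum of Sq`[-1], err_ss),
    F = c(dr$`F value`[-1], NA),
    p_value = c(dr$`Pr(>F)`[-1], NA),
    row.names = c("coloration_group", "log_cs", "log_cs_sq", "Error"))
  new_fit_result("GLM: RSM ~ coloration group + size + size^2 (partial SS)",
                 tab, list(model = fit, error_df = err_df))
}

#' Non-allometric component of the RSM
#'
#' Residuals of the quadratic regression of the RSM on log centroid size —
#' the size-corrected RSM used for coloration-group comparisons from a
#' phylogenetic perspective.  Residuals have mean zero and are orthogonal
#' to the intercept, the size covariate and its square.
#'
#' @param rsm,log_cs Numeric vectors (n > 3).
#' @return Numeric residual vector (named if `rsm` is named).
#' @export
nonallometric_residuals <- function(rsm, log_cs) {
  stopifnot(length(rsm) == length(log_cs), length(rsm) > 3)
  r <- stats::residuals(stats::lm(rsm ~ log_cs + I(log_cs^2)))
  names(r) <- names(rsm)
  r
}
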