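#' Fourth-root age transform
#'
#' Developmental time is modelled on the `(age_days + offset)^(1/4)` scale,
#' which expands infancy (where expression change is fastest) and
#' compresses adulthood. The offset (default 1 day) keeps the transform
#' finite-sloped at birth.
#'
#' @param age_days Non-negative ages in days.
#' @param offset Days added before the fourth root (default 1).
#' @return Transformed ages, strictly increasing in `age_days`.
#' @export
age_transform <- function(age_days, offset = 1) {
  if (any(age_days < 0)) rlang::abort("`age_days` must be non-negative.")
  (age_days + offset)^(1 / 4)
}

# Raw polynomial design matrix (with intercept) of the given degree.
poly_design <- function(x, degree) {
  stats::model.matrix(~ stats::poly(x, degree = degree, raw = TRUE))
}

fit_lm_rss <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Select the best polynomial age-trajectory model by adjusted R-squared
#'
#' Fits polynomials of every degree in `degrees` (default 0..3) of
#' expression on transformed age and returns the member maximizing
#' adjusted R-squared; exact ties (within `tol`) are broken toward the
#' lower degree.
#'
#' @param y Numeric response (expression of one gene).
#' @param ages Ages in days (transformed internally via [age_transform()]
#'   unless `transform = FALSE`).
#' @param degrees Candidate polynomial degrees (default `0:3`).
#' @param transform Apply the fourth-root age transform (default `TRUE`).
#' @param offset Offset for [age_transform()].
#' @param tol Tie tolerance on adjusted R-squared.
#' @return A `trajectory_fit` list: `kind = "polynomial"`, `degree`,
#'   `coefficients`, `adjusted_r2` (vector over candidate degrees with the
#'   selected one named), `rss`, `n`, `range` (fitted transformed-age
#'   range) and the transformed ages/fitted values.
#' @export
fit_polynomial_family <- function(y, ages, degrees = 0:3, transform = TRUE,
                                  offset = 1, tol = 1e-9) {
  x <- if (transform) age_transform(ages, offset) else as.numeric(ages)
  n <- length(y)
  if (length(x) != n) rlang::abort("`y` and `ages` lengths differ.")
  degrees <- sort(unique(degrees))
  feasible <- degrees[n >= degrees + 2]
  if (!length(feasible)) rlang::abort("too few samples for any candidate degree.")
  tss <- sum((y - mean(y))^2)
  fits <- lapply(feasible, function(d) {
    X <- if (d == 0) matrix(1, n, 1) else poly_design(x, d)
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    p <- d + 1
    # adjusted R^2; degenerate when y is constant (tss = 0): call it 0 so
    # the tie-break lands on degree 0
    adj <- if (tss == 0) 0 else 1 - (rss / (n - p)) / (tss / (n - 1))
    list(degree = d, coef = fit$coefficients, rss = rss, adj = adj)
  })
  adj <- vapply(fits, `[[`, 0, "adj")
  best <- which(adj >= max(adj) - tol)[1] # lowest degree among ties
  sel <- fits[[best]]
  structure(
    list(
      kind = "polynomial", degree = sel$degree,
      coefficients = sel$coef,
      adjusted_r2 = stats::setNames(adj, paste0("degree", feasible)),
      rss = sel$rss, n = n,
      range = range(x), x = x, y = y,
      fitted = drop(
        (if (sel$degree == 0) matrix(1, n, 1) else poly_design(x, sel$degree)) %*% sel$coef
      )
    ),
    class = "trajectory_fit"
  )
}

ns_basis <- function(x, df = 3, knots_from = x) {
  # natural cubic regression spline basis: df columns, interior knots at
  # age quantiles, boundary knots at the observed range
  bk <- range(knots_from)
  k <- stats::quantile(knots_from, probs = seq_len(df - 1) / df, names = FALSE)
  splines::ns(x, knots = k, Boundary.knots = bk)
}

#' Fit a 3-df natural cubic spline trajectory
#'
#' Cubic spline regression of expression on transformed age restricted to
#' three degrees of freedom (natural cubic basis, interior knots at age
#' quantiles), used for interpolation and curve comparison.
#'
#' @inheritParams fit_polynomial_family
#' @param df Spline degrees of freedom (default 3).
#' @return A `trajectory_fit` with `kind = "spline3df"` that can be
#'   evaluated anywhere in the fitted range via [predict_trajectory()].
#' @export
fit_spline3df <- function(y, ages, df = 3, transform = TRUE, offset = 1) {
  x <- if (transform) age_transform(ages, offset) else as.numeric(ages)
  if (length(y) != length(x)) rlang::abort("`y` and `ages` lengths differ.")
  if (length(y) < df + 2) rlang::abort("need at least df + 2 samples.")
  if (length(unique(x)) < df + 1) {
    rlang::abort("too few distinct age values for a 3-df spline.")
  }
  B <- ns_basis(x, df = df)
  X <- cbind(1, B)
  fit <- stats::lm.fit(X, y)
  structure(
    list(
      kind = "spline3df", degree = NA_integer_, df = df,
      coefficients = fit$coefficients,
      rss = sum(fit$residuals^2),
      adjusted_r2 = {
        tss <- sum((y - mean(y))^2)
        if (tss == 0) 0 else 1 - (sum(fit$residuals^2) / (length(y) - df - 1)) / (tss / (length(y) - 1))
      },
      n = length(y), range = range(x), x = x, y = y,
      knots = attr(B, "knots"), boundary = attr(B, "Boundary.knots"),
      fitted = drop(X %*% fit$coefficients)
    ),
    class = "trajectory_fit"
  )
}

#' Evaluate a fitted trajectory at transformed ages
#'
#' @param fit A `trajectory_fit` from [fit_polynomial_family()] or
#'   [fit_spline3df()].
#' @param x_new Transformed-age values inside the fitted range.
#' @param allow_extrapolation Permit evaluation outside the fitted range
#'   (default `FALSE`; trajectories are never extrapolated in analysis).
#' @return Numeric predictions.
#' @export
predict_trajectory <- function(fit, x_new, allow_extrapolation = FALSE) {
  stopifnot(inherits(fit, "trajectory_fit"))
  if (!allow_extrapolation &&
    (min(x_new) < fit$range[1] - 1e-8 || max(x_new) > fit$range[2] + 1e-8)) {
    rlang::abort("requested ages outside the fitted range (no extrapolation).")
  }
  if (fit$kind == "polynomial") {
    X <- if (fit$degree == 0) matrix(1, length(x_new), 1) else poly_design(x_new, fit$degree)
  } else {
    B <- splines::ns(x_new, knots = fit$knots, Boundary.knots = fit$boundary)
    X <- cbind(1, B)
  }
  drop(X %*% fit$coefficients)
}

#' Interpolate a fitted curve on an equally spaced age grid
#'
#' @param fit A `trajectory_fit`.
#' @param n_points Number of grid points (default 15), endpoints included.
#' @param range Transformed-age interval to cover; defaults to the fitted
#'   range and must lie within it.
#' @return An `interpolated_curve`: list with `grid` and `values`.
#' @export
interpolate_curve <- function(fit, n_points = 15, range = NULL) {
  range <- range %||% fit$range
  if (range[1] < fit$range[1] - 1e-8 || range[2] > fit$range[2] + 1e-8) {
    rlang::abort("interpolation range outside the fitted range.")
  }
  if (n_points < 2) rlang::abort("need at least 2 grid points.")
  grid <- seq(range[1], range[2], length.out = n_points)
  structure(
    list(grid = grid, values = predict_trajectory(fit, grid)),
    class = "interpolated_curve"
  )
}

#' Pearson correlation between two interpolated curves
#'
#' @param curve_a,curve_b `interpolated_curve` objects (or plain numeric
#'   vectors) on grids of identical length.
#' @return Pearson r in `[-1, 1]`, or `NA` with a warning if either curve
#'   is constant (undefined correlation is flagged, never coerced to 0).
#' @export
curve_correlation <- function(curve_a, curve_b) {
  va <- if (inherits(curve_a, "interpolated_curve")) curve_a$values else as.numeric(curve_a)
  vb <- if (inherits(curve_b, "interpolated_curve")) curve_b$values else as.numeric(curve_b)
  if (length(va) != length(vb)) rlang::abort("curves have different grid lengths.")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    rlang::warn("constant curve: correlation undefined.")
    return(NA_real_)
  }
  stats::cor(va, vb)
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf(
    "<trajectory_fit> %s%s, n = %d, RSS = %.4g\n",
    x$kind, if (x$kind == "polynomial") paste0(" degree ", x$degree) else "",
    x$n, x$rss
  ))
  invisible(x)
}

#' Tidy a trajectory fit
#'
#' @param x A `trajectory_fit`.
#' @param ... Unused.
#' @return One-row tibble per coefficient.
#' @export
tidy.trajectory_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients) %||% paste0("b", seq_along(x$coefficients) - 1),
    estimate = unname(x$coefficients)
  )
}

#' Glance at a trajectory fit
#'
#' @param x A `trajectory_fit`.
#' @param ... Unused.
#' @return One-row tibble with kind, degree, adjusted R-squared, RSS, n.
#' @export
glance.trajectory_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, degree = x$degree,
    adjusted_r2 = max(x$adjusted_r2), rss = x$rss, n = x$n
  )
}
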