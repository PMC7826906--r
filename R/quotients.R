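# Quotients of information transmission rate to fluctuation level.
#
# At fixed jumping parameter s the source is parameterized by p10 alone
# (p01 = s - p10). Two quotients are studied as functions of p10:
#
#   Q_sigma(p10) = ITR / sigma
#                = sqrt((s-p10)/p10) f(p10) + sqrt(p10/(s-p10)) f(s-p10)
#   Q_V(p10)     = ITR / variance
#                = s [ f(p10)/p10 + f(s-p10)/(s-p10) ]
#
# with f the chosen entropy variant. Both are symmetric about p10 = s/2.
# The exact interval endpoints are 0/0 forms, so the quotients are
# defined on the open admissible interval and the endpoint behaviour is
# supplied by the closed-form limit functions below.

check_interior_p10 <- function(s, p10) {
  bounds <- admissible_interval(s)
  bad <- p10 <= bounds[1] | p10 >= bounds[2]
  if (anyNA(p10) || any(bad)) {
    stop(sprintf(paste0("p10 must lie strictly inside (%g, %g) for s = %g; ",
                        "use q_sigma_boundary_limit()/q_variance_boundary_limit() ",
                        "for the endpoint values"),
                 bounds[1], bounds[2], s), call. = FALSE)
  }
  p10
}

#' Quotient of transmission rate to standard deviation
#'
#' \deqn{Q_\sigma(p_{1|0}) = \sqrt{\frac{s - p_{1|0}}{p_{1|0}}} f(p_{1|0})
#'   + \sqrt{\frac{p_{1|0}}{s - p_{1|0}}} f(s - p_{1|0}),}
#' equal to `markov_itr(.) / markov_sigma(.)` for the Shannon variant.
#' Symmetric about `p10 = s/2`, where it attains its maximum
#' [q_sigma_center()].
#'
#' @param s jumping parameter, `0 < s < 2`.
#' @param p10 numeric vector of transition probabilities strictly inside
#'   the admissible interval `(max(0, s-1), min(1, s))`.
#' @param variant an [entropy_variant()] or its kind as a string.
#' @return numeric vector of quotient values (dimensionless).
#' @examples
#' q_sigma(1, 0.5)          # 2, the global maximum
#' q_sigma(0.5, 0.25)       # 2 * shannon_h(0.25)
#' @export
q_sigma <- function(s, p10, variant = "shannon") {
  check_s(s)
  p10 <- check_interior_p10(s, p10)
  variant <- as_entropy_variant(variant)
  q <- s - p10
  sqrt(q / p10) * entropy_eval(variant, p10) +
    sqrt(p10 / q) * entropy_eval(variant, q)
}

#' Quotient of transmission rate to variance
#'
#' \deqn{Q_V(p_{1|0}) = s \left[ \frac{f(p_{1|0})}{p_{1|0}} +
#'   \frac{f(s - p_{1|0})}{s - p_{1|0}} \right],}
#' equal to `markov_itr(.) / markov_variance(.)` for the Shannon variant,
#' and satisfying `q_variance * sigma = q_sigma` pointwise. Under the
#' unimodal variant it is constant in `p10`, equal to `4 s (2 - s)`.
#'
#' @inheritParams q_sigma
#' @return numeric vector of quotient values (dimensionless).
#' @examples
#' q_variance(1, 0.5)                  # 4
#' q_variance(0.5, 0.2, "unimodal")    # 4 * 0.5 * 1.5 = 3
#' @export
q_variance <- function(s, p10, variant = "shannon") {
  check_s(s)
  p10 <- check_interior_p10(s, p10)
  variant <- as_entropy_variant(variant)
  q <- s - p10
  s * (entropy_eval(variant, p10) / p10 + entropy_eval(variant, q) / q)
}

#' Center (symmetry-point) value of Q_sigma
#'
#' At the symmetry point `p10 = s/2` the quotient `Q_sigma` attains its
#' maximum `2 f(s/2)`. Over all `s` this center value is maximal at
#' `s = 1`, where it equals 2: the rate never exceeds twice the
#' fluctuation level, with equality only for the fair Bernoulli source.
#'
#' @inheritParams q_sigma
#' @return the maximum of `Q_sigma` at fixed `s`.
#' @export
q_sigma_center <- function(s, variant = "shannon") {
  check_s(s)
  2 * entropy_eval(as_entropy_variant(variant), s / 2)
}

#' Boundary limit of Q_sigma
#'
#' The common limit of `Q_sigma` as `p10` approaches either endpoint of
#' the admissible interval: 0 for `s < 1` (the quotient collapses), and
#' `f(s-1) / sqrt(s-1)` for `s > 1` (the quotient stays separated from
#' zero). The Bernoulli case `s = 1` sits between the two regimes and is
#' rejected.
#'
#' @inheritParams q_sigma
#' @return the limiting quotient value at the interval endpoints.
#' @export
q_sigma_boundary_limit <- function(s, variant = "shannon") {
  check_s(s)
  if (s == 1) {
    stop("s = 1 (Bernoulli source) separates the two boundary regimes; ",
         "the limit is not defined by either closed form", call. = FALSE)
  }
  if (s < 1) return(0)
  entropy_eval(as_entropy_variant(variant), s - 1) / sqrt(s - 1)
}

#' Two-sided bounds on Q_sigma for anti-persistent sources
#'
#' For `1 < s < 2` the quotient is pinched between its boundary limit and
#' its center value:
#' \deqn{\frac{H(s-1)}{\sqrt{s-1}} \le Q_\sigma(p_{1|0}) \le 2 H(s/2),}
#' which bounds the transmission rate by multiples of the fluctuation
#' level sigma.
#'
#' @param s jumping parameter in `(1, 2)`.
#' @return named numeric vector `c(lower, upper)` (Shannon entropy).
#' @export
q_sigma_bounds <- function(s) {
  check_s(s)
  if (s <= 1) {
    stop("the two-sided bound holds for 1 < s < 2 only (for s < 1 the ",
         "quotient tends to 0 at the boundary)", call. = FALSE)
  }
  c(lower = shannon_h(s - 1) / sqrt(s - 1),
    upper = 2 * shannon_h(s / 2))
}

#' Boundary limit of Q_V
#'
#' As `p10` approaches either endpoint, `Q_V` diverges to `+Inf` for
#' `s < 1` (under the Shannon and Taylor variants; the unimodal variant is
#' constant) and tends to the finite value `s f(s-1) / (s-1)` for
#' `s > 1`.
#'
#' @inheritParams q_sigma
#' @return the limiting value, possibly `Inf`.
#' @export
q_variance_boundary_limit <- function(s, variant = "shannon") {
  check_s(s)
  if (s == 1) {
    stop("s = 1 (Bernoulli source) separates the two boundary regimes; ",
         "the limit is not defined by either closed form", call. = FALSE)
  }
  variant <- as_entropy_variant(variant)
  if (s < 1) {
    # f(p)/p diverges as p -> 0+ for the entropy-like variants except the
    # plain unimodal map, for which f(p)/p -> 4 and Q_V is constant.
    if (variant$kind == "unimodal") return(4 * s * (2 - s))
    return(Inf)
  }
  s * entropy_eval(variant, s - 1) / (s - 1)
}

new_critical_result <- function(value, residual, bracket, what) {
  structure(list(value = value, residual = residual, bracket = bracket,
                 what = what),
            class = "critical_result")
}

#' @export
print.critical_result <- function(x, ...) {
  cat(sprintf("%s = %.10g (residual %.3g, bracket [%g, %g])\n",
              x$what, x$value, x$residual, x$bracket[1], x$bracket[2]))
  invisible(x)
}

solve_bracketed <- function(f, bracket, tol, what) {
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (!is.finite(flo) || !is.finite(fhi) || sign(flo) == sign(fhi)) {
    stop("no sign change of the residual over the bracket [",
         bracket[1], ", ", bracket[2], "]", call. = FALSE)
  }
  root <- stats::uniroot(f, bracket, tol = .Machine$double.eps^0.75)$root
  # polish by bisection until the residual itself is below tol
  lo <- bracket[1]; hi <- bracket[2]
  if (sign(f(root)) == sign(flo)) lo <- root else hi <- root
  x <- root
  while (abs(f(x)) >= tol && (hi - lo) > .Machine$double.eps * abs(hi)) {
    x <- (lo + hi) / 2
    if (sign(f(x)) == sign(f(lo))) lo <- x else hi <- x
  }
  new_critical_result(x, abs(f(x)), bracket, what)
}

#' Critical jumping parameter of the Q_V center
#'
#' Solves \eqn{s H(s-1)/(s-1) = 4 H(s/2)} on `(1, 2)` (Shannon entropy)
#' by bracketing root-finding: the parameter at which the center value
#' `4 H(s/2)` of `Q_V` crosses its boundary limit `s H(s-1)/(s-1)`.
#' Below the root the center value lies below the boundary limit; above
#' it, above. The root is exactly 4/3 (substituting `s = 4/3` makes both
#' sides `4 H(1/3)` by symmetry of `H`), i.e. approximately 1.33. Note
#' this value-dominance crossover is distinct from the flip of the local
#' curvature at the center, which occurs near `s = 1.431` (twice the
#' root of the second derivative of `H(y)/y`).
#'
#' @param tolerance positive residual tolerance for the solver.
#' @return a `critical_result` with fields `value`, `residual`, `bracket`.
#' @examples
#' critical_s0()$value  # 1.3333...
#' @export
critical_s0 <- function(tolerance = 1e-10) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0) {
    stop("'tolerance' must be a single positive number", call. = FALSE)
  }
  g <- function(s) s * shannon_h(s - 1) / (s - 1) - 4 * shannon_h(s / 2)
  solve_bracketed(g, c(1 + 1e-6, 2 - 1e-6), tolerance, "s0")
}

#' Upper end of the guaranteed sigma < ITR regime
#'
#' For `s > 1` the infimum of `Q_sigma` over the admissible interval is
#' its boundary limit `H(s-1)/sqrt(s-1)`. This function solves
#' `H(s-1)/sqrt(s-1) = 1` on `(1.2, 2)`, returning the parameter `s*`
#' (about 1.72) at which the infimum crosses back below 1. For `s` below
#' `s*` (excluding a narrow band just above `s = 1`, where the infimum
#' has not yet risen to 1; it dips to about 0.81 at `s = 1.01`) the
#' infimum is at least 1, so the transmission rate dominates the
#' fluctuation level (`sigma < ITR`) regardless of the transition
#' probabilities forming that `s`.
#'
#' @param tolerance positive residual tolerance for the solver.
#' @return a `critical_result` with fields `value`, `residual`, `bracket`.
#' @export
sigma_itr_threshold <- function(tolerance = 1e-9) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0) {
    stop("'tolerance' must be a single positive number", call. = FALSE)
  }
  f <- function(s) shannon_h(s - 1) / sqrt(s - 1) - 1
  solve_bracketed(f, c(1.2, 2 - 1e-6), tolerance, "s*")
}

#' Sampled quotient curve at fixed s
#'
#' Evaluates `Q_sigma` or `Q_V` on a uniform grid over the open
#' admissible interval, inset from each endpoint by `eps` (the exact
#' endpoints are 0/0 forms; their values are the closed-form limits).
#' `n_points` is forced odd so the symmetry point `p10 = s/2` is always a
#' grid point.
#'
#' @param s jumping parameter, `0 < s < 2`.
#' @param variant an [entropy_variant()] or its kind as a string.
#' @param kind `"sigma"` for `Q_sigma` or `"variance"` for `Q_V`.
#' @param n_points number of grid points (at least 3; forced odd).
#' @param eps inset from each interval endpoint.
#' @return an object of class `"quotient_curve"`: a data frame with
#'   columns `p10` and `value` and attributes `s`, `variant`, `kind`,
#'   `eps`.
#' @examples
#' qc <- quotient_curve(0.5, kind = "sigma", n_points = 101)
#' count_local_extrema(qc)  # 1: the single maximum at p10 = s/2
#' @export
quotient_curve <- function(s, variant = "shannon",
                           kind = c("sigma", "variance"),
                           n_points = 1001L, eps = 1e-6) {
  check_s(s)
  kind <- match.arg(kind)
  variant <- as_entropy_variant(variant)
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 3L) {
    stop("'n_points' must be at least 3", call. = FALSE)
  }
  if (n_points %% 2L == 0L) n_points <- n_points + 1L
  bounds <- admissible_interval(s)
  if (!is.numeric(eps) || eps <= 0 || 2 * eps >= diff(bounds)) {
    stop("'eps' must be positive and smaller than half the admissible interval",
         call. = FALSE)
  }
  grid <- seq(bounds[1] + eps, bounds[2] - eps, length.out = n_points)
  values <- switch(kind,
                   sigma    = q_sigma(s, grid, variant),
                   variance = q_variance(s, grid, variant))
  structure(data.frame(p10 = grid, value = values),
            s = s, variant = variant$kind, kind = kind, eps = eps,
            class = c("quotient_curve", "data.frame"))
}

#' @export
print.quotient_curve <- function(x, ...) {
  cat(sprintf("Quotient curve Q_%s at s = %g (%s variant), %d grid points\n",
              if (attr(x, "kind") == "sigma") "sigma" else "V",
              attr(x, "s"), attr(x, "variant"), nrow(x)))
  cat(sprintf("  p10 in [%.6g, %.6g]; values in [%.6g, %.6g]\n",
              min(x$p10), max(x$p10), min(x$value), max(x$value)))
  invisible(x)
}

#' @export
plot.quotient_curve <- function(x, ...) {
  kind <- attr(x, "kind")
  ylab <- if (kind == "sigma") expression(Q[sigma]) else expression(Q[V])
  graphics::plot(x$p10, x$value, type = "l",
                 xlab = expression(p["1|0"]), ylab = ylab,
                 main = sprintf("s = %g (%s)", attr(x, "s"),
                                attr(x, "variant")), ...)
  invisible(x)
}

#' Count interior local extrema of a sampled curve
#'
#' Counts interior grid points that are strict local maxima or minima
#' after merging plateaus: grid steps whose value change is below a
#' relative tolerance are treated as flat and collapsed, so a constant
#' curve carrying only floating-point noise registers no extrema. The
#' two outermost grid points are never counted.
#'
#' @param curve a [quotient_curve()] (or any data frame with a `value`
#'   column) with at least 5 points.
#' @param tol relative plateau tolerance: steps smaller than
#'   `tol * max(abs(value), 1)` count as flat.
#' @return integer count of interior extrema.
#' @export
count_local_extrema <- function(curve, tol = 1e-9) {
  v <- curve$value
  if (length(v) < 5L) {
    stop("need at least 5 grid points to count interior extrema", call. = FALSE)
  }
  dv <- diff(v)
  d <- sign(dv)[abs(dv) > tol * max(abs(v), 1)]
  if (length(d) < 2L) return(0L)
  sum(d[-length(d)] != d[-1L])
}

#' Write a quotient curve to a delimited table
#'
#' Serializes the curve as a three-column table (`p10`, `value`,
#' `quotient_kind`) preceded by comment lines recording `s`, the entropy
#' variant, the boundary inset and the grid size. Values are written with
#' 10 significant digits.
#'
#' @param curve a [quotient_curve()] object.
#' @param path output file path (or `""` for standard output).
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_quotient_curve <- function(curve, path, format = c("tsv", "csv")) {
  stopifnot(inherits(curve, "quotient_curve"))
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  writeLines(sprintf("# s=%.10g variant=%s eps=%.3g n_points=%d",
                     attr(curve, "s"), attr(curve, "variant"),
                     attr(curve, "eps"), nrow(curve)), con)
  writeLines(paste("p10", "value", "quotient_kind", sep = sep), con)
  writeLines(paste(formatC(curve$p10, digits = 10, format = "g"),
                   formatC(curve$value, digits = 10, format = "g"),
                   attr(curve, "kind"), sep = sep), con)
  invisible(path)
}
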