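# The two-state Markov information source.
#
# States are 0 (no spike in the time bin) and 1 (spike). The source is
# fully specified by the transition probabilities p10 = P(1 | previous 0)
# and p01 = P(0 | previous 1). Their sum s = p10 + p01, the "jumping
# parameter", measures the tendency to switch states: s = 1 is the
# memoryless (Bernoulli) case, s < 1 persistent, s > 1 anti-persistent.
# The transition matrix is column-stochastic and acts on column
# probability vectors (state distribution evolves as P %*% dist).

#' Two-state Markov source parameters
#'
#' @param p10 probability of a 0 -> 1 transition per time bin.
#' @param p01 probability of a 1 -> 0 transition per time bin.
#' @return an object of class `"markov_params"` with fields `p10`, `p01`
#'   and the derived jumping parameter `s = p10 + p01`.
#' @examples
#' m <- markov_params(0.2, 0.3)
#' m$s  # 0.5
#' @seealso [markov_from_s()] for the (s, p10) parameterization.
#' @export
markov_params <- function(p10, p01) {
  p10 <- check_prob(p10, "p10")
  p01 <- check_prob(p01, "p01")
  if (length(p10) != 1L || length(p01) != 1L) {
    stop("'p10' and 'p01' must be single probabilities", call. = FALSE)
  }
  structure(list(p10 = p10, p01 = p01, s = p10 + p01),
            class = "markov_params")
}

#' @export
print.markov_params <- function(x, ...) {
  cat(sprintf("Two-state Markov source: p10 = %g, p01 = %g (s = %g)\n",
              x$p10, x$p01, x$s))
  invisible(x)
}

# Admissible p10 interval at fixed s: p01 = s - p10 must be in [0, 1].
admissible_interval <- function(s) {
  c(max(0, s - 1), min(1, s))
}

check_s <- function(s, name = "s") {
  if (!is.numeric(s) || length(s) != 1L || is.na(s)) {
    stop(sprintf("'%s' must be a single numeric value", name), call. = FALSE)
  }
  if (s <= 0 || s >= 2) {
    stop(sprintf(paste0("'%s' = %g is degenerate: the chain has a unique ",
                        "stationary distribution only for 0 < s < 2 ",
                        "(s = 0: two absorbing states; s = 2: period-2 chain)"),
                 name, s), call. = FALSE)
  }
  s
}

#' Build a Markov source from the jumping parameter
#'
#' Parameterizes the source by `(s, p10)` with `p01 = s - p10`. For
#' `s <= 1` the admissible range of `p10` is `[0, s]`; for `s > 1` it is
#' `[s - 1, 1]`.
#'
#' @param s jumping parameter, `0 < s < 2`.
#' @param p10 probability of a 0 -> 1 transition, inside the admissible
#'   range for this `s`.
#' @return a [markov_params()] object.
#' @examples
#' markov_from_s(0.5, 0.2)  # p01 = 0.3
#' @export
markov_from_s <- function(s, p10) {
  check_s(s)
  if (!is.numeric(p10) || length(p10) != 1L || is.na(p10)) {
    stop("'p10' must be a single numeric value", call. = FALSE)
  }
  bounds <- admissible_interval(s)
  if (p10 < bounds[1] - PROB_SLOP || p10 > bounds[2] + PROB_SLOP) {
    stop(sprintf("p10 = %g outside the admissible interval [%g, %g] for s = %g",
                 p10, bounds[1], bounds[2], s), call. = FALSE)
  }
  p10 <- pmin(pmax(p10, bounds[1]), bounds[2])
  markov_params(p10, s - p10)
}

#' Transition matrix of the source
#'
#' Returns the 2x2 column-stochastic transition matrix (columns indexed by
#' the current state 0, 1; rows by the next state), so that the state
#' distribution evolves as `P %*% dist`.
#'
#' @param params a [markov_params()] object.
#' @return a 2x2 numeric matrix with columns summing to 1.
#' @export
transition_matrix <- function(params) {
  stopifnot(inherits(params, "markov_params"))
  matrix(c(1 - params$p10, params$p10,
           params$p01, 1 - params$p01),
         nrow = 2, dimnames = list(c("0", "1"), c("0", "1")))
}

#' Stationary distribution of the source
#'
#' The unique fixed point of the master equation for `0 < s < 2`:
#' `Peq(0) = p01 / s`, `Peq(1) = p10 / s`.
#'
#' @param params a [markov_params()] object with `0 < s < 2`.
#' @return named numeric vector `c(peq0, peq1)` summing to 1.
#' @examples
#' stationary_dist(markov_params(0.2, 0.3))  # c(0.6, 0.4)
#' @export
stationary_dist <- function(params) {
  stopifnot(inherits(params, "markov_params"))
  check_s(params$s)
  c(peq0 = params$p01 / params$s, peq1 = params$p10 / params$s)
}

#' One step of the master equation
#'
#' Advances a state-probability vector one time bin:
#' `dist_{n+1} = P %*% dist_n` with the column-stochastic transition
#' matrix of [transition_matrix()].
#'
#' @param dist numeric vector `c(pn0, pn1)` of nonnegative probabilities
#'   summing to 1.
#' @param params a [markov_params()] object.
#' @return the advanced probability vector, summing to 1.
#' @export
master_step <- function(dist, params) {
  stopifnot(inherits(params, "markov_params"))
  if (!is.numeric(dist) || length(dist) != 2L || anyNA(dist)) {
    stop("'dist' must be a numeric vector of two probabilities", call. = FALSE)
  }
  if (any(dist < -PROB_SLOP) || abs(sum(dist) - 1) > 1e-9) {
    stop("'dist' must be nonnegative and sum to 1", call. = FALSE)
  }
  out <- c((1 - params$p10) * dist[1] + params$p01 * dist[2],
           params$p10 * dist[1] + (1 - params$p01) * dist[2])
  unname(out)
}

#' Information transmission rate of the Markov source
#'
#' The entropy rate of the chain in bits per symbol,
#' \deqn{ITR = P_{eq}(0) f(p_{1|0}) + P_{eq}(1) f(p_{0|1}),}
#' where \eqn{f} is the chosen entropy variant. With the Shannon variant
#' this is the exact entropy rate; with the polynomial surrogates it is
#' the corresponding generalized rate.
#'
#' @param params a [markov_params()] object with `0 < s < 2`.
#' @param variant an [entropy_variant()] or its kind as a string.
#' @return rate in bits per symbol (dimensionless analogue for the
#'   unimodal variants).
#' @examples
#' markov_itr(markov_params(0.2, 0.3))  # 0.785673...
#' @export
markov_itr <- function(params, variant = "shannon") {
  peq <- stationary_dist(params)
  variant <- as_entropy_variant(variant)
  unname(peq[1] * entropy_eval(variant, params$p10) +
         peq[2] * entropy_eval(variant, params$p01))
}

#' Information transmission rate of a Bernoulli source
#'
#' The memoryless special case `s = 1`: the rate is the binary entropy of
#' the spiking probability, `H2(p)`.
#'
#' @param p probability of a spike (state 1) per time bin.
#' @return rate in bits per symbol.
#' @export
bernoulli_itr <- function(p) {
  shannon_h(p)
}

#' Stationary standard deviation of the emitted bits
#'
#' For a 0/1-valued stationary source the standard deviation is
#' \eqn{\sigma = \sqrt{P_{eq}(0) P_{eq}(1)} = \sqrt{(s - p_{1|0}) p_{1|0}} / s}.
#' It is at most 1/2, attained when the two states are equally occupied.
#'
#' @param params a [markov_params()] object with `0 < s < 2`.
#' @return standard deviation (dimensionless, in `[0, 0.5]`).
#' @examples
#' markov_sigma(markov_params(0.2, 0.3))  # sqrt(0.24)
#' @export
markov_sigma <- function(params) {
  peq <- stationary_dist(params)
  sqrt(peq[["peq0"]] * peq[["peq1"]])
}

#' Stationary variance of the emitted bits
#'
#' `markov_sigma(params)^2 = Peq(0) * Peq(1)`.
#'
#' @inheritParams markov_sigma
#' @return variance (dimensionless, in `[0, 0.25]`).
#' @export
markov_variance <- function(params) {
  peq <- stationary_dist(params)
  peq[["peq0"]] * peq[["peq1"]]
}

#' Capacity of the symmetric channel at jumping parameter s
#'
#' For the symmetric case `p10 = p01 = s/2` the source corresponds to a
#' binary symmetric channel with crossover probability `s/2`, whose
#' capacity is `1 - H2(s/2)` bits per symbol.
#'
#' @param s jumping parameter, `0 < s < 2`.
#' @return capacity in bits per symbol.
#' @examples
#' channel_capacity(1)    # 0: crossover 1/2 transmits nothing
#' channel_capacity(0.4)  # 1 - shannon_h(0.2)
#' @export
channel_capacity <- function(s) {
  if (!is.numeric(s) || anyNA(s)) {
    stop("'s' must be numeric with no NA values", call. = FALSE)
  }
  if (any(s <= 0 | s >= 2)) {
    stop("'s' must lie strictly inside (0, 2)", call. = FALSE)
  }
  1 - shannon_h(s / 2)
}
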