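# Seeded trajectory simulation and empirical estimators.
#
# These close the loop on the analytic formulas: a long stationary
# trajectory from the chain should have RMS near sigma and a plug-in
# block-entropy rate near the closed-form ITR.

#' Simulate a binary trajectory from a Markov source
#'
#' The first state is drawn from the stationary distribution (so the
#' process is stationary from the first bin) and subsequent states follow
#' the transition probabilities. Identical `(params, n, seed)` yield a
#' bit-identical trajectory.
#'
#' @param params a [markov_params()] object with `0 < s < 2`.
#' @param n trajectory length in time bins (`n >= 1`).
#' @param seed integer RNG seed; recorded on the returned object.
#' @return an integer 0/1 vector of class `"markov_trajectory"` with
#'   attributes `seed` and `params`.
#' @examples
#' x <- simulate_markov(markov_params(0.2, 0.3), 1000, seed = 1)
#' mean(x)  # near Peq(1) = 0.4
#' @export
simulate_markov <- function(params, n, seed) {
  stopifnot(inherits(params, "markov_params"))
  check_s(params$s)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be at least 1", call. = FALSE)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  peq1 <- params$p10 / params$s
  x0 <- as.integer(stats::runif(1) < peq1)
  bits <- .simulate_chain(n, x0, params$p10, params$p01)
  structure(bits, seed = as.integer(seed), params = params,
            class = "markov_trajectory")
}

as_bits <- function(traj) {
  bits <- as.integer(unclass(traj))
  if (length(bits) < 1L || anyNA(bits) || any(bits != 0L & bits != 1L)) {
    stop("trajectory must be a nonempty 0/1 sequence", call. = FALSE)
  }
  bits
}

#' @export
print.markov_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Binary Markov trajectory: n = %d, seed = %s\n",
              length(x), format(attr(x, "seed"))))
  if (!is.null(p)) {
    cat(sprintf("  source: p10 = %g, p01 = %g (s = %g)\n", p$p10, p$p01, p$s))
  }
  cat(sprintf("  fraction of 1s: %.4f\n", mean(unclass(x))))
  invisible(x)
}

#' Root-mean-square fluctuation of a trajectory
#'
#' The population RMS about the trajectory's own mean,
#' \eqn{\sqrt{\frac{1}{n}\sum_k (x_k - \bar{x})^2}}: the empirical
#' counterpart of the stationary standard deviation [markov_sigma()].
#'
#' @param traj a [simulate_markov()] trajectory or any 0/1 vector.
#' @return the RMS (dimensionless, in `[0, 0.5]` for 0/1 data).
#' @export
trajectory_rms <- function(traj) {
  bits <- as_bits(traj)
  m <- mean(bits)
  sqrt(mean((bits - m)^2))  # = sqrt(m (1 - m)) for 0/1 data
}

#' Distribution of overlapping binary words
#'
#' Counts all `n - L + 1` overlapping windows of length `L` in the
#' trajectory. Words are encoded as their binary strings.
#'
#' @param traj a [simulate_markov()] trajectory or any 0/1 vector.
#' @param L word length in bins, `1 <= L <= n`.
#' @return an object of class `"word_distribution"`: a list with `counts`
#'   (named integer vector over observed words), `word_length` and
#'   `total`.
#' @examples
#' word_distribution(c(0L, 1L, 1L, 0L), 2)  # words 01, 11, 10
#' @export
word_distribution <- function(traj, L) {
  bits <- as_bits(traj)
  L <- as.integer(L)
  n <- length(bits)
  if (is.na(L) || L < 1L || L > n) {
    stop(sprintf("'L' must satisfy 1 <= L <= n = %d", n), call. = FALSE)
  }
  if (L > 30L) {
    stop("'L' above 30 is not supported (word table of 2^L cells)",
         call. = FALSE)
  }
  codes <- word_codes(bits, L)
  counts <- tabulate(codes + 1L, nbins = 2L^L)
  observed <- which(counts > 0L)
  words <- vapply(observed - 1L, function(code) {
    paste(as.integer(intToBits(code))[L:1], collapse = "")
  }, character(1))
  structure(list(counts = stats::setNames(counts[observed], words),
                 word_length = L, total = n - L + 1L),
            class = "word_distribution")
}

# Integer code of each overlapping length-L window (leftmost bit most
# significant), via an FIR filter evaluated in C.
word_codes <- function(bits, L) {
  if (L == 1L) return(bits)
  # sides = 1 filtering reaches backwards in time, so the earliest bit of
  # each window gets the highest weight: codes read in time order.
  codes <- stats::filter(bits, 2^(0:(L - 1L)), method = "convolution",
                         sides = 1)
  as.integer(round(codes[L:length(bits)]))
}

#' @export
print.word_distribution <- function(x, ...) {
  cat(sprintf("Word distribution: L = %d, %d observed words, %d windows\n",
              x$word_length, length(x$counts), x$total))
  invisible(x)
}

#' Plug-in block entropy
#'
#' The Shannon entropy, in bits, of the empirical word distribution:
#' \eqn{-\sum_w \hat{P}(w) \log_2 \hat{P}(w)} over the observed words
#' (unobserved words contribute 0 by the \eqn{0 \log 0} convention). No
#' bias correction is applied.
#'
#' @param dist a [word_distribution()] object.
#' @return block entropy in bits.
#' @export
block_entropy <- function(dist) {
  stopifnot(inherits(dist, "word_distribution"))
  p <- dist$counts / dist$total
  -sum(p * log2(p))
}

#' Empirical information transmission rate
#'
#' Estimates the entropy rate of the source behind a trajectory from its
#' block entropies \eqn{\hat{H}(Z^L)}:
#' `"block_average"` returns \eqn{\hat{H}(Z^L)/L}, the finite-`L` rate,
#' which overestimates the limit for autocorrelated sources;
#' `"conditional"` returns \eqn{\hat{H}(Z^L) - \hat{H}(Z^{L-1})}, which
#' for a Markov source converges to the limit already at `L = 2` and is
#' the default.
#'
#' A hard error is raised when `n < 2^L` (more word types than windows);
#' a warning when `n < 50 * 2^L`, where plug-in bias is appreciable.
#'
#' @param traj a [simulate_markov()] trajectory or any 0/1 vector.
#' @param L word length in bins (`L >= 2` for `"conditional"`).
#' @param method `"conditional"` (default) or `"block_average"`.
#' @return estimated rate in bits per symbol.
#' @export
itr_estimate <- function(traj, L, method = c("conditional", "block_average")) {
  bits <- as_bits(traj)
  method <- match.arg(method)
  L <- as.integer(L)
  n <- length(bits)
  min_L <- if (method == "conditional") 2L else 1L
  if (is.na(L) || L < min_L || L > n) {
    stop(sprintf("'L' must satisfy %d <= L <= n for method '%s'",
                 min_L, method), call. = FALSE)
  }
  if (n < 2^L) {
    stop(sprintf("undersampled: n = %d trajectory cannot resolve 2^%d words",
                 n, L), call. = FALSE)
  }
  if (n < 50 * 2^L) {
    warning(sprintf("n = %d is below 50 * 2^L; the plug-in estimate at L = %d will be biased",
                    n, L), call. = FALSE)
  }
  hL <- block_entropy(word_distribution(bits, L))
  if (method == "block_average") return(hL / L)
  hL - block_entropy(word_distribution(bits, L - 1L))
}

#' Analytic-versus-empirical closure report
#'
#' Simulates a trajectory, estimates its rate (conditional block-entropy
#' estimator) and RMS, and tabulates them against the closed-form ITR and
#' sigma of the generating source.
#'
#' @param params a [markov_params()] object with `0 < s < 2`.
#' @param n trajectory length.
#' @param seed integer RNG seed.
#' @param L word length for the rate estimator; default: the largest `L`
#'   with `n >= 50 * 2^L`, capped at 12 (keeps plug-in bias well below
#'   the Monte-Carlo spread at the default lengths).
#' @return a one-row data frame with columns `p10`, `p01`, `s`, `n`,
#'   `seed`, `L`, `itr_analytic`, `itr_empirical`, `sigma_analytic`,
#'   `rms`, `abs_dev_itr`, `abs_dev_sigma`.
#' @examples
#' \donttest{
#' empirical_check(markov_params(0.2, 0.3), n = 1e5, seed = 7)
#' }
#' @export
empirical_check <- function(params, n, seed, L = NULL) {
  stopifnot(inherits(params, "markov_params"))
  n <- as.integer(n)
  if (is.null(L)) {
    L <- min(12L, max(2L, floor(log2(n / 50))))
  }
  L <- as.integer(L)
  traj <- simulate_markov(params, n, seed)
  itr_emp <- itr_estimate(traj, L, method = "conditional")
  rms <- trajectory_rms(traj)
  itr_an <- markov_itr(params, "shannon")
  sig_an <- markov_sigma(params)
  data.frame(p10 = params$p10, p01 = params$p01, s = params$s,
             n = n, seed = as.integer(seed), L = L,
             itr_analytic = itr_an, itr_empirical = itr_emp,
             sigma_analytic = sig_an, rms = rms,
             abs_dev_itr = abs(itr_emp - itr_an),
             abs_dev_sigma = abs(rms - sig_an))
}
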