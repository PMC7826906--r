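# Binary entropy and its polynomial surrogates.
#
# All four functions are symmetric about p = 1/2, attain their maximum 1
# there, and are used interchangeably as the per-state "H" inside the
# Markov entropy-rate formula (see markov_itr).

VARIANT_KINDS <- c("shannon", "taylor10", "unimodal", "unimodal_root")

# Inputs may arrive with floating-point slop from upstream arithmetic
# (e.g. s - p10 evaluating to -1e-17); violations below this are clamped,
# anything larger is a caller error.
PROB_SLOP <- 1e-12

check_prob <- function(p, name = deparse(substitute(p))) {
  if (!is.numeric(p) || anyNA(p)) {
    stop(sprintf("'%s' must be numeric with no NA values", name), call. = FALSE)
  }
  bad <- p < -PROB_SLOP | p > 1 + PROB_SLOP
  if (any(bad)) {
    stop(sprintf("'%s' must lie in [0, 1]; offending value: %.17g",
                 name, p[bad][1L]), call. = FALSE)
  }
  pmin(pmax(p, 0), 1)
}

#' Binary Shannon entropy
#'
#' Computes \eqn{H_2(p) = -p \log_2 p - (1-p) \log_2 (1-p)}, the entropy in
#' bits of a Bernoulli(\eqn{p}) symbol, with the convention
#' \eqn{0 \log_2 0 = 0} so that the endpoints return exactly 0.
#'
#' @param p numeric vector of probabilities in \eqn{[0, 1]}.
#' @return numeric vector of entropies in bits, in \eqn{[0, 1]}.
#' @examples
#' shannon_h(0.5)   # 1 bit
#' shannon_h(0.25)  # 0.811278...
#' @seealso [taylor_h()], [unimodal_u()], [unimodal_root()], [entropy_eval()]
#' @export
shannon_h <- function(p) {
  p <- check_prob(p)
  out <- numeric(length(p))
  i <- p > 0 & p < 1
  out[i] <- -p[i] * log2(p[i]) - (1 - p[i]) * log2(1 - p[i])
  out
}

#' Truncated Taylor series of the binary entropy
#'
#' The binary entropy expanded about its maximum at \eqn{p = 1/2}:
#' \deqn{H_2(p) = 1 - \frac{1}{\ln 4} \sum_{n \ge 1}
#'   \frac{(1-2p)^{2n}}{n(2n-1)},}
#' truncated after `n_terms` terms of the sum. With the default 10 terms
#' the truncation stays within 0.02 of the exact entropy on the whole unit
#' interval (the deviation is concentrated at the endpoints, where the
#' series converges slowest).
#'
#' @param p numeric vector of probabilities in \eqn{[0, 1]}.
#' @param n_terms number of series terms retained (positive integer).
#' @return numeric vector of approximate entropies in bits.
#' @examples
#' taylor_h(0.25)            # close to shannon_h(0.25)
#' taylor_h(0.25, n_terms = 1)  # 1 - 0.25 / log(4)
#' @export
taylor_h <- function(p, n_terms = 10L) {
  p <- check_prob(p)
  n_terms <- as.integer(n_terms)
  if (length(n_terms) != 1L || is.na(n_terms) || n_terms < 1L) {
    stop("'n_terms' must be a single positive integer", call. = FALSE)
  }
  x2 <- (1 - 2 * p)^2
  acc <- numeric(length(p))
  term <- rep(1, length(p))
  for (n in seq_len(n_terms)) {
    term <- term * x2
    acc <- acc + term / (n * (2 * n - 1))
  }
  1 - acc / log(4)
}

#' Unimodal map surrogate for the binary entropy
#'
#' The logistic (unimodal) map \eqn{U(p) = 4p(1-p)}, a polynomial that
#' shares the symmetry, endpoints and maximum of the binary entropy and is
#' within 0.12 of it in supremum norm.
#'
#' @param p numeric vector of probabilities in \eqn{[0, 1]}.
#' @return numeric vector in \eqn{[0, 1]} (dimensionless).
#' @export
unimodal_u <- function(p) {
  p <- check_prob(p)
  4 * p * (1 - p)
}

#' Square root of the unimodal map
#'
#' \eqn{\sqrt{U(p)} = 2\sqrt{p(1-p)}}, a tighter surrogate for the binary
#' entropy near the endpoints than the unimodal map itself.
#'
#' @param p numeric vector of probabilities in \eqn{[0, 1]}.
#' @return numeric vector in \eqn{[0, 1]} (dimensionless).
#' @export
unimodal_root <- function(p) {
  p <- check_prob(p)
  2 * sqrt(p * (1 - p))
}

#' Entropy-variant selector
#'
#' Bundles the choice of entropy-like function used as the per-state "H"
#' in the Markov entropy-rate formula and in the fluctuation quotients.
#'
#' @param kind one of `"shannon"`, `"taylor10"`, `"unimodal"`,
#'   `"unimodal_root"`.
#' @param n_terms number of series terms for the `"taylor10"` variant
#'   (ignored otherwise).
#' @return an object of class `"entropy_variant"`.
#' @examples
#' v <- entropy_variant("unimodal")
#' entropy_eval(v, 0.25)  # 0.75
#' @export
entropy_variant <- function(kind = VARIANT_KINDS, n_terms = 10L) {
  kind <- match.arg(kind)
  n_terms <- as.integer(n_terms)
  if (length(n_terms) != 1L || is.na(n_terms) || n_terms < 1L) {
    stop("'n_terms' must be a single positive integer", call. = FALSE)
  }
  structure(list(kind = kind, n_terms = n_terms),
            class = "entropy_variant")
}

as_entropy_variant <- function(variant) {
  if (inherits(variant, "entropy_variant")) return(variant)
  if (is.character(variant) && length(variant) == 1L) {
    return(entropy_variant(variant))
  }
  stop("'variant' must be an entropy_variant object or one of: ",
       paste(VARIANT_KINDS, collapse = ", "), call. = FALSE)
}

#' @export
print.entropy_variant <- function(x, ...) {
  cat("Entropy variant:", x$kind)
  if (x$kind == "taylor10") cat(" (", x$n_terms, " series terms)", sep = "")
  cat("\n")
  invisible(x)
}

#' Evaluate an entropy variant
#'
#' Dispatches to [shannon_h()], [taylor_h()], [unimodal_u()] or
#' [unimodal_root()] according to the variant's kind. Shannon and Taylor
#' results are in bits; the unimodal variants are dimensionless analogues.
#'
#' @param variant an [entropy_variant()] object or its kind as a string.
#' @param p numeric vector of probabilities in \eqn{[0, 1]}.
#' @return numeric vector of the same length as `p`.
#' @export
entropy_eval <- function(variant, p) {
  variant <- as_entropy_variant(variant)
  switch(variant$kind,
         shannon       = shannon_h(p),
         taylor10      = taylor_h(p, variant$n_terms),
         unimodal      = unimodal_u(p),
         unimodal_root = unimodal_root(p),
         stop("unknown entropy variant kind: ", variant$kind, call. = FALSE))
}
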