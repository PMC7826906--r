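# Standard figures: the entropy surrogates overlay and the two-panel
# quotient plots (panel A: persistent sources s <= 1, panel B:
# anti-persistent sources s > 1). Base graphics; callers direct output
# to a device (e.g. png()) themselves or via cmd_figures().

DEFAULT_S_A <- c(0.3, 0.5, 0.8)
DEFAULT_S_B <- c(1.2, 1.3, 1.5, 1.8)

#' Overlay of the binary entropy and its polynomial surrogates
#'
#' Draws the Shannon entropy together with the 10-term Taylor truncation,
#' the unimodal map and its square root on a dense grid of `p`.
#'
#' @param n_points grid resolution.
#' @return invisibly, the data frame of plotted values.
#' @export
plot_entropy_variants <- function(n_points = 501L) {
  p <- seq(0, 1, length.out = n_points)
  dat <- data.frame(p = p,
                    shannon = shannon_h(p),
                    taylor10 = taylor_h(p),
                    unimodal = unimodal_u(p),
                    unimodal_root = unimodal_root(p))
  graphics::matplot(dat$p, dat[, -1], type = "l",
                    lty = c(1, 4, 2, 3), col = c("black", "grey40", "black", "black"),
                    lwd = c(2, 1.5, 1.5, 1.5),
                    xlab = "p", ylab = "H(p) and surrogates",
                    main = "Binary entropy and polynomial surrogates")
  graphics::legend("bottom", legend = names(dat)[-1],
                   lty = c(1, 4, 2, 3), col = c("black", "grey40", "black", "black"),
                   lwd = c(2, 1.5, 1.5, 1.5), bty = "n")
  invisible(dat)
}

#' Two-panel plot of a fluctuation quotient
#'
#' Panel A shows the quotient curves for persistent sources (`s <= 1`,
#' admissible range `p10 in (0, s)`), panel B for anti-persistent
#' sources (`1 < s < 2`, range `(s-1, 1)`).
#'
#' @param kind `"sigma"` for `Q_sigma` or `"variance"` for `Q_V`.
#' @param s_a,s_b jumping-parameter values for panels A and B.
#' @param variant entropy variant used inside the quotient.
#' @param n_points grid resolution per curve.
#' @return invisibly, the list of [quotient_curve()]s plotted.
#' @export
plot_quotient_panels <- function(kind = c("sigma", "variance"),
                                 s_a = DEFAULT_S_A, s_b = DEFAULT_S_B,
                                 variant = "shannon", n_points = 501L) {
  kind <- match.arg(kind)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  qname <- if (kind == "sigma") "ITR/sigma" else "ITR/V"
  draw <- function(svals, label) {
    curves <- lapply(svals, quotient_curve, variant = variant, kind = kind,
                     n_points = n_points)
    ylim <- range(vapply(curves, function(cv) range(cv$value), numeric(2)))
    xlim <- range(vapply(curves, function(cv) range(cv$p10), numeric(2)))
    graphics::plot(NA, xlim = xlim, ylim = ylim,
                   xlab = expression(p["1|0"]), ylab = qname,
                   main = sprintf("(%s) %s variant", label, variant))
    for (i in seq_along(curves)) {
      graphics::lines(curves[[i]]$p10, curves[[i]]$value, lty = i)
    }
    graphics::legend("topright", legend = sprintf("s = %g", svals),
                     lty = seq_along(svals), bty = "n", cex = 0.8)
    curves
  }
  out <- c(draw(s_a, "A"), draw(s_b, "B"))
  invisible(out)
}
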