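# Bias-source diagnostics: ENC-plot with the expected curve, PR2 plot, and
# the neutrality (GC12 ~ GC3) regression.

#' Expected ENC under pure compositional drive
#'
#' The position a gene should occupy on the ENC-plot were its codon usage
#' determined only by third-position composition:
#' `ENC_exp = 2 + s + 29 / (s^2 + (1 - s)^2)` with `s = GC3s`.
#' The curve is maximal at s = 0.5 (value 60.5) and takes the values 31 at
#' s = 0 and 32 at s = 1.
#'
#' @param gc3s GC3s value(s) in [0, 1].
#' @return Expected ENC, vectorized over `gc3s`.
#' @export
enc_expected <- function(gc3s) {
  if (any(is.na(gc3s)) || any(gc3s < 0 | gc3s > 1)) {
    stop("gc3s must lie in [0, 1]")
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' ENC-plot table
#'
#' One point per gene with defined ENC and GC3s: observed ENC, the expected
#' ENC at the gene's GC3s, and the deviation `ENC_exp - ENC_obs`. Positive
#' deviation places the gene below the expected curve, the pattern read as
#' selection on codon usage beyond compositional drive.
#'
#' @param profiles Profile data.frame from [profile_genes()].
#' @return data.frame `gene`, `GC3s`, `ENC_obs`, `ENC_exp`, `deviation`,
#'   with attribute `n_skipped` (genes lacking ENC or GC3s).
#' @export
enc_plot_table <- function(profiles) {
  stopifnot(is.data.frame(profiles), all(c("gene", "ENC", "GC3s") %in% names(profiles)))
  ok <- !is.na(profiles$ENC) & !is.na(profiles$GC3s)
  if (!any(ok)) stop("no genes with defined ENC and GC3s")
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    message(n_skipped, " gene(s) without defined ENC/GC3s skipped from ENC-plot")
  }
  p <- profiles[ok, , drop = FALSE]
  out <- data.frame(
    gene = p$gene,
    GC3s = p$GC3s,
    ENC_obs = p$ENC,
    ENC_exp = enc_expected(p$GC3s),
    stringsAsFactors = FALSE
  )
  out$deviation <- out$ENC_exp - out$ENC_obs
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' PR2 (parity rule 2) plot coordinates
#'
#' Per-gene third-position skews over synonymous codons:
#' x = G3 / (G3 + C3), y = A3 / (A3 + T3). Under strand-symmetric usage
#' (A = T, G = C) genes sit at the centre (0.5, 0.5); displacement marks the
#' direction and degree of third-base bias. Coordinates with a zero
#' denominator are `NA` and counted.
#'
#' @param profiles Profile data.frame from [profile_genes()].
#' @return data.frame `gene`, `x`, `y` with attribute `n_undefined`.
#' @export
pr2_table <- function(profiles) {
  stopifnot(
    is.data.frame(profiles),
    all(c("gene", "A3", "T3", "G3", "C3") %in% names(profiles))
  )
  if (nrow(profiles) == 0L) stop("no profiles")
  gc_den <- profiles$G3 + profiles$C3
  at_den <- profiles$A3 + profiles$T3
  out <- data.frame(
    gene = profiles$gene,
    x = ifelse(gc_den > 0, profiles$G3 / gc_den, NA_real_),
    y = ifelse(at_den > 0, profiles$A3 / at_den, NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_undefined") <- sum(is.na(out$x) | is.na(out$y))
  out
}

#' Neutrality-plot regression
#'
#' Ordinary least squares of GC12 (mean GC at codon positions 1 and 2) on
#' GC3, with the Pearson correlation and its two-sided p-value (t
#' distribution, n - 2 df). A slope near 1 indicates mutation-dominated
#' codon usage (positions evolving in concert with third-position
#' composition); a slope near 0 indicates selection holding first/second
#' positions steady.
#'
#' @param profiles data.frame with columns `GC12` and `GC3` (e.g. from
#'   [profile_genes()] or [simulate_neutrality_panel()]).
#' @return A `neutrality_fit` object: `n_genes`, `slope`, `intercept`,
#'   `slope_se`, `pearson_r`, `p_value`, `gc12_range`, `gc3_range`, `model`
#'   (the underlying `lm` fit).
#' @export
neutrality_fit <- function(profiles) {
  stopifnot(is.data.frame(profiles), all(c("GC12", "GC3") %in% names(profiles)))
  ok <- !is.na(profiles$GC12) & !is.na(profiles$GC3)
  gc12 <- profiles$GC12[ok]
  gc3 <- profiles$GC3[ok]
  n <- length(gc3)
  if (n < 3L) stop("neutrality fit needs >= 3 genes with defined GC12 and GC3")
  if (stats::var(gc3) == 0) stop("degenerate regressor: GC3 is constant")
  fit <- stats::lm(gc12 ~ gc3)
  r <- stats::cor(gc3, gc12)
  if (abs(r) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  out <- list(
    n_genes = n,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    # an exactly collinear input is legitimate here (e.g. GC12 == GC3);
    # silence lm's perfect-fit warning when extracting the slope SE
    slope_se = suppressWarnings(summary(fit)$coefficients[2L, 2L]),
    pearson_r = r,
    p_value = p,
    gc12_range = range(gc12),
    gc3_range = range(gc3),
    model = fit
  )
  class(out) <- "neutrality_fit"
  out
}

#' @export
print.neutrality_fit <- function(x, digits = 4, ...) {
  cat("Neutrality plot regression (GC12 ~ GC3), n =", x$n_genes, "genes\n")
  cat(
    "  slope =", signif(x$slope, digits),
    "(se", paste0(signif(x$slope_se, digits), ")"),
    " intercept =", signif(x$intercept, digits), "\n"
  )
  cat(
    "  Pearson r =", signif(x$pearson_r, digits),
    " p =", format.pval(x$p_value, digits = digits), "\n"
  )
  cat(
    "  GC12 in [", paste(signif(x$gc12_range, digits), collapse = ", "), "]",
    " GC3 in [", paste(signif(x$gc3_range, digits), collapse = ", "), "]\n"
  )
  invisible(x)
}

#' @export
coef.neutrality_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Plot a neutrality fit
#'
#' Scatter of GC12 against GC3 with the fitted line and the GC12 = GC3
#' diagonal.
#'
#' @param x A `neutrality_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.neutrality_fit <- function(x, ...) {
  d <- x$model$model
  graphics::plot(d$gc3, d$gc12,
    xlab = "GC3", ylab = "GC12",
    pch = 20, col = "grey40", ...
  )
  graphics::abline(0, 1, lty = 2, col = "red")
  graphics::abline(x$intercept, x$slope, col = "blue", lwd = 2)
}

#' Plot an ENC-plot table
#'
#' Observed ENC against GC3s with the expected-ENC curve.
#'
#' @param tab Output of [enc_plot_table()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_enc <- function(tab, ...) {
  graphics::plot(tab$GC3s, tab$ENC_obs,
    xlab = "GC3s", ylab = "ENC",
    xlim = c(0, 1), ylim = c(15, 62), pch = 20, col = "grey40", ...
  )
  s <- seq(0, 1, length.out = 200L)
  graphics::lines(s, enc_expected(s), col = "red", lwd = 2)
}

#' Plot PR2 coordinates
#'
#' @param tab Output of [pr2_table()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_pr2 <- function(tab, ...) {
  graphics::plot(tab$x, tab$y,
    xlab = "G3 / (G3 + C3)", ylab = "A3 / (A3 + T3)",
    xlim = c(0, 1), ylim = c(0, 1), pch = 20, col = "grey40", ...
  )
  graphics::abline(h = 0.5, v = 0.5, lty = 2, col = "red")
}
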