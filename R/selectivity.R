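#' pK_D of a dissociation constant
#'
#' `pK_D = -log10(K_D / 1 M)`; larger means tighter binding (0.1 uM gives
#' 7.0, 200 uM gives ~3.7).
#'
#' @param kd Dissociation constant(s) in mol/L, > 0.
#' @return Numeric vector of pK_D values.
#' @export
pkd <- function(kd) {
  if (any(!is.finite(kd) | kd <= 0)) stop("`kd` must be positive (mol/L)")
  -log10(kd)
}

#' Per-interface affinity records
#'
#' Assembles and validates the (site, K_D, pK_D, P_hb) table consumed by
#' the selectivity regression and the interface ranking.
#'
#' @param site_id Character labels of the interfaces (e.g. "beta+/alpha-").
#' @param kd_molar Dissociation constants in mol/L.
#' @param phb Hydrogen-bond probabilities in `[0, 1]`.
#' @return Data frame with columns `site_id`, `kd_molar`, `pkd`, `phb`.
#' @export
interface_affinities <- function(site_id, kd_molar, phb) {
  if (length(site_id) != length(kd_molar) || length(site_id) != length(phb)) {
    stop("`site_id`, `kd_molar` and `phb` must have equal length")
  }
  if (any(!is.finite(phb) | phb < 0 | phb > 1)) stop("`phb` must lie in [0, 1]")
  data.frame(site_id = as.character(site_id), kd_molar = kd_molar,
             pkd = pkd(kd_molar), phb = phb, stringsAsFactors = FALSE)
}

#' Fit the selectivity line pK_D = a P_hb + b
#'
#' Ordinary least squares of per-interface pK_D on hydrogen-bond
#' probability, with standard errors from the residual variance, the
#' explained-variance r^2, and a 95% confidence band for the mean response
#' using the t-quantile at n - 2 degrees of freedom. With the typical
#' four interfaces the band is wide (2 residual degrees of freedom) --
#' this is a feature of the data, not of the fit.
#'
#' @param records Data frame from [interface_affinities()] (columns `pkd`,
#'   `phb`; a `kd_molar` column is used to derive `pkd` if absent).
#' @param weights Optional per-record weights for sensitivity analysis;
#'   the default fit is unweighted.
#' @return An object of class `selectivity_fit`: `a`, `b`, `se_a`, `se_b`,
#'   `r2`, `n`, and the underlying `lm` fit.
#' @seealso [confidence_band()], [rank_interfaces()]
#' @export
fit_pkd_vs_phb <- function(records, weights = NULL) {
  records <- as.data.frame(records)
  if (is.null(records$pkd)) {
    if (is.null(records$kd_molar)) stop("records need `pkd` or `kd_molar`")
    records$pkd <- pkd(records$kd_molar)
  }
  if (is.null(records$phb)) stop("records need a `phb` column")
  if (nrow(records) < 2L) stop("need at least 2 records")
  if (length(unique(records$phb)) < 2L) {
    stop("degenerate design: all P_hb values identical")
  }
  fit <- if (is.null(weights)) {
    stats::lm(pkd ~ phb, data = records)
  } else {
    stats::lm(pkd ~ phb, data = records, weights = weights)
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(
    list(a = unname(cf["phb"]), b = unname(cf["(Intercept)"]),
         se_a = unname(se["phb"]), se_b = unname(se["(Intercept)"]),
         r2 = summary(fit)$r.squared, n = nrow(records),
         lm = fit, records = records),
    class = "selectivity_fit"
  )
}

#' @export
print.selectivity_fit <- function(x, ...) {
  cat(sprintf(
    "selectivity_fit: pK_D = a P_hb + b; a = %.3g +/- %.2g, b = %.3g +/- %.2g, r^2 = %.3f (n = %d)\n",
    x$a, x$se_a, x$b, x$se_b, x$r2, x$n))
  invisible(x)
}

#' Confidence band of the fitted selectivity line
#'
#' Mean-response ("confidence") band of the fitted line at the requested
#' P_hb values, symmetric about the line and narrowest at the mean P_hb of
#' the data.
#'
#' @param fit A `selectivity_fit`.
#' @param phb P_hb values at which to evaluate the band.
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `phb`, `fit`, `lwr`, `upr`.
#' @export
confidence_band <- function(fit, phb, level = 0.95) {
  stopifnot(inherits(fit, "selectivity_fit"))
  p <- stats::predict(fit$lm, newdata = data.frame(phb = phb),
                      interval = "confidence", level = level)
  data.frame(phb = phb, fit = p[, "fit"], lwr = p[, "lwr"], upr = p[, "upr"])
}

#' Rank interfaces by affinity
#'
#' Orders records by descending affinity (ascending K_D) and reports the
#' pairwise K_D ratios and the log10 gap between the strongest and weakest
#' site -- the "orders of magnitude" separating the selective interfaces.
#'
#' @param records Data frame with `site_id` and `kd_molar` columns.
#' @return List with `ranked` (the reordered records), `kd_ratio` (matrix
#'   of pairwise ratios, row / column) and `log10_gap`.
#' @export
rank_interfaces <- function(records) {
  records <- as.data.frame(records)
  if (!nrow(records)) stop("need at least 1 record")
  ord <- order(records$kd_molar)
  ranked <- records[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  kd <- ranked$kd_molar
  ratio <- outer(kd, kd, "/")
  dimnames(ratio) <- list(ranked$site_id, ranked$site_id)
  list(ranked = ranked, kd_ratio = ratio,
       log10_gap = log10(max(kd) / min(kd)))
}

#' Plot the selectivity regression
#'
#' Scatter of pK_D against P_hb with the fitted line and its mean-response
#' confidence band.
#'
#' @param fit A `selectivity_fit`.
#' @param level Band confidence level.
#' @param ... Passed to [graphics::plot()].
#' @return The band data frame, invisibly.
#' @export
plot_selectivity <- function(fit, level = 0.95, ...) {
  stopifnot(inherits(fit, "selectivity_fit"))
  rec <- fit$records
  grid <- seq(min(rec$phb), max(rec$phb), length.out = 100)
  band <- confidence_band(fit, grid, level)
  graphics::plot(rec$phb, rec$pkd, xlab = expression(P[hb]),
                 ylab = expression(pK[D]),
                 ylim = range(c(band$lwr, band$upr, rec$pkd)), ...)
  graphics::polygon(c(grid, rev(grid)), c(band$lwr, rev(band$upr)),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::abline(fit$b, fit$a)
  graphics::points(rec$phb, rec$pkd, pch = 19)
  invisible(band)
}
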