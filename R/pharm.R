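#' Fit a variable-slope Hill (sigmoidal dose-response) curve
#'
#' Least-squares fit of
#' \deqn{y = bottom + \frac{top - bottom}{1 + (EC_{50}/c)^{h}}}
#' with the Hill slope `h` free. The curve is parameterized internally in
#' `log(EC50)` and fitted with Levenberg-Marquardt; starting values come
#' from a deterministic log-grid scan over EC50 and a small set of Hill
#' slopes, so the fit is reproducible given the data. A negative fitted
#' `h` describes a descending curve (e.g. competitive displacement), with
#' `top` still the upper plateau.
#'
#' Confidence intervals are asymptotic by default (t-quantile at `n - p`
#' degrees of freedom, EC50 interval formed on the log scale); a seeded
#' residual bootstrap is available instead.
#'
#' @param concentration Dose vector (mol/L or any fixed unit), > 0.
#' @param response Response vector, same length.
#' @param fix Optional named list fixing any of `top`, `bottom`, `hill`.
#' @param level Confidence level (default 0.95).
#' @param ci_method `"asymptotic"` (default) or `"bootstrap"`.
#' @param n_boot,boot_seed Bootstrap replicates and seed.
#' @return An object of class `hill_fit`: `ec50`, `hill`, `top`,
#'   `bottom`, `ci` (data frame of lower/upper bounds per free parameter),
#'   `sigma`, `fitted`, `residuals`, and the underlying `nls` object.
#' @examples
#' c0 <- 10^seq(-7, -4, length.out = 8)
#' y <- 1 / (1 + (1e-5 / c0))
#' fit_hill(c0, y)$ec50  # 1e-5
#' @export
fit_hill <- function(concentration, response, fix = NULL, level = 0.95,
                     ci_method = c("asymptotic", "bootstrap"),
                     n_boot = 500, boot_seed = 1L) {
  ci_method <- match.arg(ci_method)
  conc <- as.numeric(concentration)
  y <- as.numeric(response)
  if (length(conc) != length(y)) stop("lengths of dose and response differ")
  if (any(!is.finite(conc)) || any(conc <= 0)) stop("doses must be positive")
  if (any(!is.finite(y))) stop("responses must be finite")
  if (stats::sd(y) < 1e-12 * (abs(mean(y)) + 1)) {
    stop("degenerate data: responses are flat")
  }
  free <- setdiff(c("log_ec50", "hill", "top", "bottom"),
                  c(if (!is.null(fix$hill)) "hill",
                    if (!is.null(fix$top)) "top",
                    if (!is.null(fix$bottom)) "bottom"))
  if (length(unique(conc)) < length(free)) {
    stop("need at least as many distinct doses as free parameters")
  }
  # deterministic start: coarse scan over log-spaced EC50 and Hill slopes
  hill_grid <- if (is.null(fix$hill)) c(-4, -2, -1, -0.5, 0.5, 1, 2, 4)
               else fix$hill
  ec50_grid <- exp(seq(log(min(conc) / 10), log(max(conc) * 10),
                       length.out = 25))
  top0 <- if (is.null(fix$top)) max(y) else fix$top
  bot0 <- if (is.null(fix$bottom)) min(y) else fix$bottom
  best <- NULL
  for (h in hill_grid) for (e in ec50_grid) {
    pred <- bot0 + (top0 - bot0) / (1 + exp(h * (log(e) - log(conc))))
    rss <- sum((y - pred)^2)
    if (is.null(best) || rss < best$rss) best <- list(rss = rss, h = h, e = e)
  }
  start <- list(log_ec50 = log(best$e), hill = best$h, top = top0,
                bottom = bot0)[free]
  env <- list2env(list(conc = conc, y = y))
  for (nm in names(fix)) assign(nm, fix[[nm]], envir = env)
  form <- y ~ bottom + (top - bottom) / (1 + exp(hill * (log_ec50 - log(conc))))
  fit <- tryCatch(
    minpack.lm::nlsLM(form, start = start,
                      data = env,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Hill fit did not converge: ",
                             conditionMessage(e)))
  est <- as.list(stats::coef(fit))
  for (nm in names(fix)) est[[nm]] <- fix[[nm]]
  ci <- hill_ci(fit, est, free, conc, y, level, ci_method, n_boot, boot_seed,
                fix)
  structure(
    list(ec50 = exp(est$log_ec50), hill = est$hill, top = est$top,
         bottom = est$bottom, ci = ci, level = level,
         sigma = summary(fit)$sigma, fitted = stats::fitted(fit),
         residuals = stats::residuals(fit), nls = fit,
         ci_method = ci_method),
    class = "hill_fit"
  )
}

hill_ci <- function(fit, est, free, conc, y, level, ci_method, n_boot,
                    boot_seed, fix) {
  p <- length(free)
  n <- length(y)
  if (ci_method == "asymptotic") {
    se <- sqrt(diag(stats::vcov(fit)))
    tq <- stats::qt(1 - (1 - level) / 2, df = n - p)
    lower <- unlist(est[free]) - tq * se[free]
    upper <- unlist(est[free]) + tq * se[free]
  } else {
    set.seed(as.integer(boot_seed))
    res <- stats::residuals(fit)
    yhat <- stats::fitted(fit)
    draws <- matrix(NA_real_, n_boot, length(free),
                    dimnames = list(NULL, free))
    for (b in seq_len(n_boot)) {
      yb <- yhat + sample(res, replace = TRUE)
      fb <- tryCatch(
        minpack.lm::nlsLM(stats::formula(fit), start = as.list(stats::coef(fit)),
                          data = list2env(c(list(conc = conc, y = yb), fix))),
        error = function(e) NULL)
      if (!is.null(fb)) draws[b, ] <- stats::coef(fb)[free]
    }
    qs <- apply(draws, 2, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
    lower <- qs[1, ]
    upper <- qs[2, ]
  }
  out <- data.frame(parameter = free, estimate = unlist(est[free]),
                    lower = lower, upper = upper, row.names = NULL)
  # report EC50 on the natural scale
  i <- out$parameter == "log_ec50"
  out$parameter[i] <- "ec50"
  out[i, c("estimate", "lower", "upper")] <-
    exp(out[i, c("estimate", "lower", "upper")])
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  ec <- x$ci[x$ci$parameter == "ec50", ]
  cat(sprintf(
    "hill_fit: EC50 = %.3g (%g%% CI %.3g - %.3g), hill = %.3g, top = %.3g, bottom = %.3g\n",
    x$ec50, 100 * x$level, ec$lower, ec$upper, x$hill, x$top, x$bottom))
  invisible(x)
}

#' Effective concentration at a response fraction
#'
#' Inverts the Hill curve: the dose giving fraction `fraction` of the
#' top-bottom span is `EC50 (fraction / (1 - fraction))^(1/hill)`; e.g.
#' the EC10 used to set a submaximal agonist baseline.
#'
#' @param ec50 Half-maximal concentration.
#' @param hill Hill slope (nonzero).
#' @param fraction Response fraction in (0, 1); default 0.1 (EC10).
#' @return Concentration in the unit of `ec50`.
#' @export
ec_fraction <- function(ec50, hill, fraction = 0.1) {
  if (any(fraction <= 0 | fraction >= 1)) stop("`fraction` must be in (0, 1)")
  if (any(hill == 0)) stop("`hill` must be nonzero")
  ec50 * (fraction / (1 - fraction))^(1 / hill)
}

#' Cheng-Prusoff correction of a displacement IC50
#'
#' Converts a competition IC50 into the inhibitor dissociation constant,
#' correcting for the presence of the reporter probe:
#' \deqn{K_D = IC_{50} / (1 + [probe]/K_D^{probe}).}
#' Reduces to `IC50` when no probe is present and to `IC50/2` at probe
#' concentration equal to the probe's own K_D.
#'
#' @param ic50 Measured half-maximal displacement concentration (> 0).
#' @param probe_conc Probe concentration (>= 0), same unit as `probe_kd`.
#' @param probe_kd Probe dissociation constant (> 0).
#' @return Corrected dissociation constant, same unit as `ic50`.
#' @export
cheng_prusoff <- function(ic50, probe_conc, probe_kd) {
  if (any(ic50 <= 0) || any(probe_kd <= 0) || any(probe_conc < 0)) {
    stop("inputs must be positive (probe_conc may be zero)")
  }
  ic50 / (1 + probe_conc / probe_kd)
}

#' Fit a single-exponential decay
#'
#' Least-squares fit of `A(t) = A0 exp(-k t)` (optionally plus a constant
#' floor) with `k` kept positive through a `log(k)` parameterization.
#' Reports the decay half-life `t_half = ln 2 / k` with its confidence
#' interval transformed from the `log(k)` interval. Flat data are flagged
#' as the `k -> 0` boundary rather than fitted.
#'
#' @param times Time points (>= 3), e.g. minutes.
#' @param values Positive decaying signal (e.g. absorbance).
#' @param floor Include an additive floor term?
#' @param level Confidence level.
#' @return An object of class `decay_fit`: `k`, `t_half`, `amplitude`,
#'   `floor`, `ci` (for `k` and `t_half`), `boundary` flag, `sigma`, and
#'   the underlying `nls` object (`NULL` at the boundary).
#' @examples
#' t <- seq(0, 50, by = 5)
#' fit_exp_decay(t, 2 * exp(-log(2) / 25 * t))$t_half  # 25
#' @export
fit_exp_decay <- function(times, values, floor = FALSE, level = 0.95) {
  t <- as.numeric(times)
  y <- as.numeric(values)
  if (length(t) != length(y)) stop("lengths of times and values differ")
  if (length(t) < 3L) stop("need at least 3 time points")
  if (any(!is.finite(t)) || any(!is.finite(y))) stop("inputs must be finite")
  if (all(y <= 0)) stop("values must contain positive signal")
  if (stats::sd(y) < 1e-10 * (abs(mean(y)) + 1)) {
    return(structure(
      list(k = 0, t_half = Inf, amplitude = mean(y), floor = 0,
           ci = NULL, boundary = TRUE, sigma = 0, nls = NULL, level = level),
      class = "decay_fit"))
  }
  if (stats::cor(t, y) > 0) {
    stop("values are not decay-dominant (increasing trend)")
  }
  pos <- y > 0
  sl <- stats::coef(stats::lm(log(y[pos]) ~ t[pos]))
  k0 <- max(1e-6, -unname(sl[2]))
  start <- list(a0 = max(y), log_k = log(k0))
  env <- list2env(list(t = t, y = y))
  form <- if (floor) {
    start$c0 <- min(y)
    y ~ c0 + a0 * exp(-exp(log_k) * t)
  } else {
    y ~ a0 * exp(-exp(log_k) * t)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, start = start, data = env,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("decay fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tq <- stats::qt(1 - (1 - level) / 2, df = length(y) - length(cf))
  k <- exp(cf[["log_k"]])
  k_ci <- exp(cf[["log_k"]] + c(-1, 1) * tq * se[["log_k"]])
  ci <- data.frame(
    parameter = c("k", "t_half"),
    estimate = c(k, log(2) / k),
    lower = c(k_ci[1], log(2) / k_ci[2]),
    upper = c(k_ci[2], log(2) / k_ci[1]))
  structure(
    list(k = k, t_half = log(2) / k, amplitude = cf[["a0"]],
         floor = if (floor) cf[["c0"]] else 0,
         ci = ci, boundary = FALSE, sigma = summary(fit)$sigma, nls = fit,
         level = level),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$boundary) {
    cat("decay_fit: flat signal, k at the 0 boundary (t_half = Inf)\n")
  } else {
    th <- x$ci[x$ci$parameter == "t_half", ]
    cat(sprintf("decay_fit: t_half = %.3g (%g%% CI %.3g - %.3g), k = %.3g\n",
                x$t_half, 100 * x$level, th$lower, th$upper, x$k))
  }
  invisible(x)
}
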