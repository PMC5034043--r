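#' Gaussian work samples with known free energy
#'
#' Draws per-window perturbation energies from a normal distribution, for
#' which exponential averaging has the closed form
#' \deqn{\Delta G = \mu - \sigma^2 / (2RT),}
#' attached as ground truth. Exercises the Zwanzig estimator end to end.
#'
#' @param mu,sigma Mean and SD of the work distribution (kcal/mol);
#'   `sigma >= 0`.
#' @param n Sample count.
#' @param seed Integer seed.
#' @param thermo A [thermo_state()] (or temperature in kelvin).
#' @return List with `samples` (a [window_samples()] spanning lambda 1 ->
#'   0), `truth` (`dg`, `mu`, `sigma`) and `seed`.
#' @export
gen_work_samples <- function(mu, sigma, n, seed = 1L,
                             thermo = thermo_state()) {
  thermo <- as_thermo(thermo)
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (n < 1) stop("`n` must be >= 1")
  set.seed(as.integer(seed))
  x <- if (sigma == 0) rep(mu, n) else stats::rnorm(n, mu, sigma)
  list(samples = window_samples(1, 0, x),
       truth = list(dg = mu - sigma^2 / (2 * thermo$rt), mu = mu,
                    sigma = sigma),
       seed = as.integer(seed))
}

#' Synthetic TMT quant table with spike-in targets
#'
#' Emulates a three-channel (UV+, UV-, protected) isobaric-tag experiment:
#' background proteins with true enrichment factor close to 1 (tight
#' log-normal, so threshold behavior is exercised), spike-in targets with
#' prescribed capture enrichment and protection, and multiplicative
#' log-normal replicate noise specified as a log2 standard deviation on
#' the channel ratios (default 0.28, a typical replicate spread for this
#' kind of experiment).
#'
#' @param n_proteins Number of background proteins.
#' @param n_replicates Replicates per protein (default 4).
#' @param spike_ins Data frame with columns `ef_capture` and
#'   `protection_pct` (one row per spiked target), or `NULL`.
#' @param log2_noise_sd Log2 SD of the per-replicate ratio noise.
#' @param background_log2_sd Log2 SD of the true background enrichment
#'   around 1.
#' @param base_intensity Median UV- reporter intensity.
#' @param seed Integer seed.
#' @return List with `quant` (protein x replicate table), `truth` (per
#'   protein: true enrichment factors and the engineered specific label at
#'   the default decision thresholds) and `seed`.
#' @export
gen_tmt_table <- function(n_proteins, n_replicates = 4, spike_ins = NULL,
                          log2_noise_sd = 0.28, background_log2_sd = 0.1,
                          base_intensity = 1e5, seed = 1L) {
  if (n_proteins < 1) stop("`n_proteins` must be >= 1")
  if (log2_noise_sd < 0 || background_log2_sd < 0) stop("noise SDs must be >= 0")
  set.seed(as.integer(seed))
  n_spike <- if (is.null(spike_ins)) 0L else nrow(spike_ins)
  ids <- c(if (n_spike) sprintf("SPIKE%03d", seq_len(n_spike)),
           sprintf("P%05d", seq_len(n_proteins)))
  true_efc <- c(if (n_spike) spike_ins$ef_capture,
                2^stats::rnorm(n_proteins, 0, background_log2_sd))
  true_prot <- c(if (n_spike) spike_ins$protection_pct,
                 rep(0, n_proteins))
  true_efp <- true_efc * (1 - true_prot / 100)
  n_all <- length(ids)
  quant <- do.call(rbind, lapply(seq_len(n_all), function(i) {
    uv_minus <- base_intensity * 2^stats::rnorm(n_replicates, 0, 0.5)
    data.frame(
      protein_id = ids[i], replicate = seq_len(n_replicates),
      uv_plus = uv_minus * true_efc[i] *
        2^stats::rnorm(n_replicates, 0, log2_noise_sd),
      uv_minus = uv_minus,
      protected = uv_minus * true_efp[i] *
        2^stats::rnorm(n_replicates, 0, log2_noise_sd),
      stringsAsFactors = FALSE)
  }))
  rownames(quant) <- NULL
  truth <- data.frame(
    protein_id = ids, true_ef_capture = true_efc,
    true_ef_protected = true_efp, true_protection_pct = true_prot,
    spiked = c(rep(TRUE, n_spike), rep(FALSE, n_proteins)),
    true_specific = true_efc > 10 & true_prot > 50 &
      (true_efc - true_efp) >= 5,
    stringsAsFactors = FALSE)
  list(quant = quant, truth = truth, seed = as.integer(seed))
}

#' Synthetic dose-response data with known Hill parameters
#'
#' @param ec50,hill,top,bottom True curve parameters.
#' @param doses Dose vector (replicated `n_per_dose` times).
#' @param sigma Additive response noise SD.
#' @param n_per_dose Replicates per dose.
#' @param seed Integer seed.
#' @return List with `data` (`concentration`, `response`, `replicate`),
#'   `truth` and `seed`.
#' @export
gen_dose_response <- function(ec50, hill, doses, sigma = 0, n_per_dose = 1,
                              top = 1, bottom = 0, seed = 1L) {
  if (any(doses <= 0)) stop("doses must be positive")
  if (sigma < 0) stop("`sigma` must be >= 0")
  set.seed(as.integer(seed))
  conc <- rep(doses, each = n_per_dose)
  mu <- bottom + (top - bottom) / (1 + (ec50 / conc)^hill)
  resp <- mu + stats::rnorm(length(conc), 0, sigma)
  list(data = data.frame(concentration = conc, response = resp,
                         replicate = rep(seq_len(n_per_dose),
                                         times = length(doses))),
       truth = list(ec50 = ec50, hill = hill, top = top, bottom = bottom,
                    sigma = sigma),
       seed = as.integer(seed))
}

#' Synthetic single-exponential photolysis decay
#'
#' @param t_half True half-life (same time unit as `times`).
#' @param a0 Initial amplitude.
#' @param times Measurement time points.
#' @param sigma Additive noise SD (absolute; e.g. `0.02 * a0` for 2%
#'   amplitude noise).
#' @param seed Integer seed.
#' @return List with `data` (`time`, `value`), `truth` and `seed`.
#' @export
gen_decay <- function(t_half, a0, times, sigma = 0, seed = 1L) {
  if (t_half <= 0 || a0 <= 0) stop("`t_half` and `a0` must be positive")
  if (sigma < 0) stop("`sigma` must be >= 0")
  set.seed(as.integer(seed))
  k <- log(2) / t_half
  val <- a0 * exp(-k * times) + stats::rnorm(length(times), 0, sigma)
  list(data = data.frame(time = times, value = val),
       truth = list(t_half = t_half, k = k, a0 = a0, sigma = sigma),
       seed = as.integer(seed))
}

#' Synthetic per-interface selectivity records on a known line
#'
#' Places interface records on the line `pK_D = a P_hb + b` (optionally
#' with Gaussian scatter in pK_D) and back-derives the dissociation
#' constants, for exercising the selectivity regression.
#'
#' @param a,b True slope and intercept of the selectivity line.
#' @param phb_values Hydrogen-bond probabilities of the records.
#' @param sigma SD of the pK_D scatter.
#' @param seed Integer seed.
#' @return List with `records` (an [interface_affinities()] data frame),
#'   `truth` and `seed`.
#' @export
gen_selectivity_records <- function(a = 3.4, b = 3.4, phb_values, sigma = 0,
                                    seed = 1L) {
  if (any(phb_values < 0 | phb_values > 1)) stop("`phb_values` must lie in [0, 1]")
  if (sigma < 0) stop("`sigma` must be >= 0")
  set.seed(as.integer(seed))
  pk <- a * phb_values + b + stats::rnorm(length(phb_values), 0, sigma)
  records <- interface_affinities(
    site_id = sprintf("S%d", seq_along(phb_values)),
    kd_molar = 10^(-pk), phb = phb_values)
  list(records = records, truth = list(a = a, b = b, sigma = sigma),
       seed = as.integer(seed))
}
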