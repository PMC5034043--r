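check_quant <- function(quant) {
  quant <- as.data.frame(quant)
  needed <- c("protein_id", "replicate", "uv_plus", "uv_minus", "protected")
  if (!all(needed %in% names(quant))) {
    stop("quant table needs columns ", paste(needed, collapse = ", "))
  }
  num <- as.matrix(quant[c("uv_plus", "uv_minus", "protected")])
  if (any(!is.finite(num)) || any(num < 0)) {
    stop("channel intensities must be finite and >= 0")
  }
  quant
}

#' Enrichment factors from a TMT quant table
#'
#' Computes, per protein, the capture enrichment factor (mean over
#' replicates of the UV+/UV- reporter-ion ratio) and the protected
#' enrichment factor (mean protected/UV- ratio), plus the derived
#' protection percentage `100 (EF_capture - EF_protected) / EF_capture`
#' and `delta EF = EF_capture - EF_protected`.
#'
#' "Mean ratio" is the mean of per-replicate ratios (the default), not the
#' ratio of summed intensities; the alternative is available via `method`
#' for sensitivity analysis. Proteins with any zero UV- denominator are
#' flagged and carry `NA` enrichment factors; they are excluded from
#' classification rather than imputed.
#'
#' @param quant Data frame with one row per protein x replicate and
#'   columns `protein_id`, `replicate`, `uv_plus`, `uv_minus`,
#'   `protected` (reporter-ion intensities, >= 0).
#' @param method `"mean_of_ratios"` (default) or `"ratio_of_sums"`.
#' @return Data frame of enrichment records: `protein_id`, `n_replicates`,
#'   `ef_capture`, `ef_protected`, `protection_pct`, `delta_ef`,
#'   `flagged`.
#' @export
enrichment_factors <- function(quant, method = c("mean_of_ratios",
                                                 "ratio_of_sums")) {
  method <- match.arg(method)
  quant <- check_quant(quant)
  split_q <- split(quant, quant$protein_id)
  recs <- lapply(split_q, function(q) {
    flagged <- any(q$uv_minus == 0)
    if (flagged) {
      efc <- efp <- NA_real_
    } else if (method == "mean_of_ratios") {
      efc <- mean(q$uv_plus / q$uv_minus)
      efp <- mean(q$protected / q$uv_minus)
    } else {
      efc <- sum(q$uv_plus) / sum(q$uv_minus)
      efp <- sum(q$protected) / sum(q$uv_minus)
    }
    data.frame(protein_id = q$protein_id[1], n_replicates = nrow(q),
               ef_capture = efc, ef_protected = efp,
               protection_pct = if (!flagged && efc > 0)
                 100 * (efc - efp) / efc else NA_real_,
               delta_ef = efc - efp, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out[match(unique(quant$protein_id), out$protein_id), , drop = FALSE]
}

#' High-capture classification
#'
#' A protein is a high-capture target when its capture enrichment factor
#' strictly exceeds the threshold (default 10).
#'
#' @param ef_capture Numeric vector of capture enrichment factors.
#' @param threshold Enrichment-factor threshold (strict inequality).
#' @return Logical vector (`NA` where the EF is undefined).
#' @export
classify_capture <- function(ef_capture, threshold = 10) {
  ef_capture > threshold
}

#' Ligand-specific protection classification
#'
#' A (high-capture) protein is ligand specific when protection exceeds
#' `pct_threshold` percent (strict) and the enrichment factor drops by at
#' least `delta_threshold` under protection.
#'
#' @param ef_capture,ef_protected Enrichment factors (capture > 0).
#' @param pct_threshold Protection percentage threshold (strict, default 50).
#' @param delta_threshold Minimum decrease in enrichment factor (default 5).
#' @return Logical vector.
#' @export
classify_protection <- function(ef_capture, ef_protected,
                                pct_threshold = 50, delta_threshold = 5) {
  protection_pct <- 100 * (ef_capture - ef_protected) / ef_capture
  protection_pct > pct_threshold &
    (ef_capture - ef_protected) >= delta_threshold
}

#' Full ABPP decision rules on an enrichment table
#'
#' Applies the two-stage classification: the capture gate (EF strictly
#' greater than `ef_threshold`) and, only for proteins passing it, the
#' protection rule (protection > `pct_threshold` percent and a decrease of
#' at least `delta_threshold` in enrichment factor). Flagged records
#' (undefined EF) are never classified and keep `NA` labels.
#'
#' @param records Enrichment records from [enrichment_factors()], or a raw
#'   quant table (then [enrichment_factors()] is applied first).
#' @param ef_threshold,pct_threshold,delta_threshold Decision thresholds.
#' @return The records with added logical columns `high_capture` and
#'   `propofol_specific` (`FALSE` for high-capture proteins failing the
#'   protection rule; `NA` where never evaluated).
#' @export
classify_abpp <- function(records, ef_threshold = 10, pct_threshold = 50,
                          delta_threshold = 5) {
  records <- as.data.frame(records)
  if (!"ef_capture" %in% names(records)) records <- enrichment_factors(records)
  hc <- classify_capture(records$ef_capture, ef_threshold)
  spec <- rep(NA, nrow(records))
  eval_idx <- !is.na(hc) & hc
  spec[eval_idx] <- classify_protection(
    records$ef_capture[eval_idx], records$ef_protected[eval_idx],
    pct_threshold, delta_threshold)
  spec[!is.na(hc) & !hc] <- FALSE
  records$high_capture <- hc
  records$propofol_specific <- spec
  records
}

#' Proteome-level summary of an ABPP experiment
#'
#' Summarizes a quant table the way quantitative ABPP experiments are
#' reported: a histogram of log2 enrichment factors, the pooled
#' replicate-agreement standard deviation of log2 channel ratios, class
#' counts at the decision thresholds, and the captured fraction of the
#' input proteome.
#'
#' @param quant Protein x replicate quant table (see
#'   [enrichment_factors()]).
#' @param bins Histogram bin count passed to [graphics::hist()].
#' @param log_base Base of the logarithm used for the distribution
#'   summaries (default 2).
#' @param ... Thresholds forwarded to [classify_abpp()].
#' @return An object of class `proteome_summary`: `n_proteins`,
#'   `n_flagged`, `log_sd_capture` (pooled replicate SD of log
#'   UV+/UV- ratios), `log_sd_protected`, `hist` (histogram of log EF),
#'   `n_high_capture`, `n_specific`, `fraction_high_capture`, and the
#'   classified `records`.
#' @export
summarize_proteome <- function(quant, bins = 30, log_base = 2, ...) {
  quant <- check_quant(quant)
  records <- classify_abpp(enrichment_factors(quant), ...)
  ok <- !records$flagged
  if (!any(ok)) stop("no records with defined enrichment factors")
  lg <- function(x) log(x, base = log_base)
  pooled_sd <- function(ratio) {
    x <- lg(ratio)
    grp <- quant$protein_id[quant$uv_minus > 0]
    dev2 <- tapply(x, grp, function(v) sum((v - mean(v))^2))
    df <- tapply(x, grp, function(v) length(v) - 1L)
    sqrt(sum(dev2) / max(1, sum(df)))
  }
  defined <- quant$uv_minus > 0
  q <- quant[defined, , drop = FALSE]
  h <- graphics::hist(lg(records$ef_capture[ok & records$ef_capture > 0]),
                      breaks = bins, plot = FALSE)
  structure(
    list(n_proteins = nrow(records), n_flagged = sum(!ok),
         log_sd_capture = pooled_sd(q$uv_plus / q$uv_minus),
         log_sd_protected = pooled_sd(q$protected / q$uv_minus),
         hist = h,
         n_high_capture = sum(records$high_capture[ok]),
         n_specific = sum(records$propofol_specific[ok], na.rm = TRUE),
         fraction_high_capture = mean(records$high_capture[ok]),
         records = records),
    class = "proteome_summary"
  )
}

#' @export
print.proteome_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "proteome_summary: %d proteins (%d flagged)\n",
    "  log2 replicate SD: capture %.3f, protected %.3f\n",
    "  high capture: %d (%.1f%%), ligand specific: %d\n"),
    x$n_proteins, x$n_flagged, x$log_sd_capture, x$log_sd_protected,
    x$n_high_capture, 100 * x$fraction_high_capture, x$n_specific))
  invisible(x)
}

#' Read / write ABPP tables
#'
#' CSV interchange for quant tables (one row per protein x replicate) and
#' enrichment-record tables.
#'
#' @param quant,records Data frames as used by [enrichment_factors()] and
#'   [classify_abpp()].
#' @param path File path.
#' @return Readers return data frames; writers return `path` invisibly.
#' @export
write_quant_csv <- function(quant, path) {
  utils::write.csv(check_quant(quant), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quant_csv
#' @export
read_quant_csv <- function(path) {
  check_quant(utils::read.csv(path))
}

#' @rdname write_quant_csv
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
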