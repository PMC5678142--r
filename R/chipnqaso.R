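# ChIPnQASO: quantitative allele-specific occupancy from KASP fluorescence.
#
# Input chromatin from a heterozygous line carries both alleles at exactly
# 50/50, so the mean per-channel input signal defines a conversion factor
# per channel. Dividing an IP well's channels by those factors and
# renormalizing yields its allelic fractions relative to input; this
# ratio-of-ratios is the unique linear correction that maps input to 50/50
# and cancels any channel-gain asymmetry shared by input and IP wells.

#' Conversion factors from input-DNA wells
#'
#' @param input_readings tibble of NTC-normalized input wells (columns `x`
#'   wildtype channel, `y` mutant channel), e.g. the `input_dna` rows of
#'   [normalize_readings()]. Multiple input wells are pooled by per-channel
#'   means.
#' @return object of class `conversion_factors`: `factor_mut`, `factor_wt`,
#'   `n_input_wells`.
#' @examples
#' compute_conversion_factors(tibble::tibble(x = 800, y = 1000))
#' @export
compute_conversion_factors <- function(input_readings) {
  if (nrow(input_readings) < 1) {
    stop_quant("at least one input well is required")
  }
  factor_mut <- mean(input_readings$y)
  factor_wt <- mean(input_readings$x)
  if (!is.finite(factor_mut) || !is.finite(factor_wt) ||
      factor_mut <= 0 || factor_wt <= 0) {
    stop_quant(sprintf(
      "input channel mean(s) not strictly positive (factor_mut=%g, factor_wt=%g); cannot normalize",
      factor_mut, factor_wt))
  }
  structure(list(factor_mut = factor_mut, factor_wt = factor_wt,
                 n_input_wells = nrow(input_readings)),
            class = "conversion_factors")
}

#' Mutant-allele fraction of one well relative to input
#'
#' `frac_mut = (y/factor_mut) / (y/factor_mut + x/factor_wt)`. An input
#' replicate evaluated against its own factors gives exactly 0.5, and any
#' well proportional to the input (same channel ratio at any scale) does
#' too.
#'
#' @param reading one NTC-normalized well: a list/one-row data.frame with
#'   `x` and `y`.
#' @param factors a [compute_conversion_factors()] result.
#' @return mutant-allele fraction in `[0, 1]`.
#' @examples
#' f <- compute_conversion_factors(tibble::tibble(x = 800, y = 1000))
#' allelic_fraction(list(x = 640, y = 1600), f)  # 2/3: a 2:1 preference
#' @export
allelic_fraction <- function(reading, factors) {
  stopifnot(inherits(factors, "conversion_factors"))
  x <- reading$x
  y <- reading$y
  if (length(x) != 1 || length(y) != 1) {
    stop_quant("allelic_fraction expects a single well; see quantify_chip() for panels")
  }
  if (x + y <= 0) stop_quant("no IP signal: well magnitude is zero")
  ym <- y / factors$factor_mut
  xw <- x / factors$factor_wt
  ym / (ym + xw)
}

#' Summarize replicate allelic fractions
#'
#' Groups per-replicate fractions by sample and antibody and reports mean,
#' sample standard deviation (0 and flagged `single_replicate` when n = 1)
#' and the allelic preference ratio `mean / (1 - mean)`. Groups whose
#' wells sat below the amplification threshold (e.g. IgG) are carried
#' through flagged `low_signal`, never dropped.
#'
#' @param quants tibble with columns `sample_id`, `antibody`, `frac_mut`
#'   and optionally logical `low_signal` per replicate.
#' @return tibble: `sample_id`, `antibody`, `n`, `mean_frac_mut`,
#'   `sd_frac_mut`, `preference_ratio`, `flags` (comma-joined, "" if none).
#' @export
summarize_replicates <- function(quants) {
  if (nrow(quants) == 0) stop_validation("no replicates to summarize")
  if (any(quants$frac_mut < 0 | quants$frac_mut > 1)) {
    stop_validation("frac_mut values must lie in [0, 1]")
  }
  if (!"low_signal" %in% names(quants)) quants$low_signal <- FALSE
  out <- summarise(
    group_by(quants, sample_id, antibody),
    n = n(),
    mean_frac_mut = mean(frac_mut),
    sd_frac_mut = if (n() >= 2) sd(frac_mut) else 0,
    low_signal = any(low_signal),
    .groups = "drop")
  out$preference_ratio <- out$mean_frac_mut / (1 - out$mean_frac_mut)
  out$flags <- apply(
    cbind(ifelse(out$n == 1, "single_replicate", NA),
          ifelse(out$low_signal, "low_signal", NA)),
    1, function(f) paste(f[!is.na(f)], collapse = ","))
  out$low_signal <- NULL
  out
}

#' Full ChIPnQASO quantitation of a panel
#'
#' Normalizes a plate against its NTCs, derives conversion factors from
#' the `input_dna` wells, converts every `input_dna`, `ip` and `igg` well
#' to allelic fractions and summarizes replicates per sample x antibody
#' (input and IgG wells are labelled `"input"` and `"IgG"`).
#'
#' @param panel a [plate_panel()] with `ntc`, `input_dna` and `ip` wells.
#' @param params a [caller_params()] (supplies the NTC threshold rule).
#' @return list: `summary` (see [summarize_replicates()]), `replicates`
#'   (per-well fractions), `factors`, `amp_threshold`.
#' @export
quantify_chip <- function(panel, params = caller_params()) {
  norm <- normalize_readings(panel)
  amp_threshold <- norm$ntc$mean_magnitude +
    params$ntc_sd_multiplier * norm$ntc$sd_magnitude
  rd <- norm$readings
  inp <- rd[rd$role == "input_dna" & rd$magnitude > amp_threshold &
              rd$x > 0 & rd$y > 0, ]
  if (nrow(inp) == 0) {
    stop_quant("no input_dna well with both channels above the amplification threshold")
  }
  factors <- compute_conversion_factors(inp)
  q <- rd[rd$role %in% c("input_dna", "ip", "igg"), ]
  q$antibody <- ifelse(q$role == "input_dna", "input",
                       ifelse(q$role == "igg", "IgG", q$antibody))
  keep <- q$magnitude > 0
  q <- q[keep, ]
  q$frac_mut <- vapply(seq_len(nrow(q)), function(i) {
    allelic_fraction(q[i, ], factors)
  }, numeric(1))
  q$low_signal <- q$magnitude <= amp_threshold
  reps <- q[, c("sample_id", "antibody", "well", "frac_mut", "low_signal")]
  list(summary = summarize_replicates(reps), replicates = reps,
       factors = factors, amp_threshold = amp_threshold)
}
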