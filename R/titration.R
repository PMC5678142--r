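# Limit-of-detection analysis for mutant-allele titration series.
#
# A titration mixes heterozygous and wildtype genomic DNA so the mutant
# allele is present at known percentages; each level is measured in
# replicate and compared against the 0% (homozygous wildtype) control by
# a two-sided pooled-variance Student's t-test. The limit of detection is
# the smallest nominal level significant at the chosen alpha.

#' Pooled-variance two-sample t-test
#'
#' Textbook Student's t with a pooled-variance floor of `1e-12` so that
#' noise-free fixtures (zero variance in both groups) yield a defined
#' statistic: equal means then give t = 0 (p = 1), different means a
#' p-value below any alpha.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @param var_floor lower bound on the pooled variance.
#' @return list: `t`, `df`, `p` (two-sided), `mean_diff`.
#' @export
pooled_t_test <- function(a, b, var_floor = 1e-12) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop_validation("each group needs at least 2 replicates")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  sp2 <- max(sp2, var_floor)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df), mean_diff = mean(a) - mean(b))
}

#' Limit-of-detection analysis of a titration series
#'
#' @param levels tibble with one row per replicate measurement: columns
#'   `nominal_percent_mut` (the known mixed-in mutant-allele percentage)
#'   and `frac_mut` (the measured mutant-allele fraction, e.g. from
#'   [allelic_fraction()]). Must include the 0% control; every level needs
#'   at least 2 replicates.
#' @param alpha significance threshold (default 0.001, a deliberately
#'   stringent single threshold; no multiplicity correction is applied
#'   across levels).
#' @return object of class `titration_result`: `per_level` tibble
#'   (`nominal_percent_mut`, `n`, `mean_frac_mut`, `t`, `df`, `p`),
#'   `lod_percent` (smallest significant level, `NA` = not detected) and
#'   `alpha`. P-values are reported as computed; they are not forced to be
#'   monotone across levels.
#' @export
lod_analysis <- function(levels, alpha = 0.001) {
  if (!all(c("nominal_percent_mut", "frac_mut") %in% names(levels))) {
    stop_validation("levels needs columns nominal_percent_mut and frac_mut")
  }
  if (any(levels$nominal_percent_mut < 0 | levels$nominal_percent_mut > 100)) {
    stop_validation("nominal_percent_mut must lie in [0, 100]")
  }
  if (any(levels$frac_mut < 0 | levels$frac_mut > 1)) {
    stop_validation("frac_mut must lie in [0, 1]")
  }
  ctrl <- levels$frac_mut[levels$nominal_percent_mut == 0]
  if (length(ctrl) < 2) {
    stop_config("a 0% control level with at least 2 replicates is required")
  }
  tested <- sort(unique(levels$nominal_percent_mut))
  tested <- tested[tested > 0]
  rows <- lapply(tested, function(lv) {
    f <- levels$frac_mut[levels$nominal_percent_mut == lv]
    if (length(f) < 2) {
      stop_config(sprintf("level %g%% has %d replicate(s); need at least 2",
                          lv, length(f)))
    }
    tt <- pooled_t_test(f, ctrl)
    tibble(nominal_percent_mut = lv, n = length(f), mean_frac_mut = mean(f),
           t = tt$t, df = tt$df, p = tt$p)
  })
  per_level <- bind_rows(
    tibble(nominal_percent_mut = 0, n = length(ctrl),
           mean_frac_mut = mean(ctrl), t = NA_real_, df = NA_real_,
           p = NA_real_),
    bind_rows(rows))
  sig <- per_level$nominal_percent_mut[!is.na(per_level$p) &
                                         per_level$p < alpha]
  structure(list(per_level = per_level,
                 lod_percent = if (length(sig) > 0) min(sig) else NA_real_,
                 alpha = alpha),
            class = "titration_result")
}

#' @export
print.titration_result <- function(x, ...) {
  cat("<titration_result> alpha =", x$alpha, "; LOD =",
      if (is.na(x$lod_percent)) "not detected"
      else paste0(x$lod_percent, "% mutant allele"), "\n")
  print(as.data.frame(x$per_level), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plan a titration plate layout
#'
#' Deterministically assigns each level x replicate to consecutive wells
#' (row-major from A1 on the 384-well grid), so a planned series
#' round-trips through the plate CSV dialect.
#'
#' @param percent_levels nominal mutant-allele percentages; must include 0.
#' @param replicates replicate wells per level (>= 1).
#' @return tibble: `well`, `sample_id`, `role` (`"clone"`),
#'   `nominal_percent_mut`, `replicate`.
#' @examples
#' nrow(mixture_series_design(c(0, 1, 2.5, 5, 10, 15, 20, 25, 50), 4)) # 36
#' @export
mixture_series_design <- function(percent_levels, replicates) {
  if (!is_count(replicates, min = 1)) {
    stop_validation("replicates must be a positive integer")
  }
  if (any(percent_levels < 0 | percent_levels > 100)) {
    stop_validation("percent levels must lie in [0, 100]")
  }
  if (!0 %in% percent_levels) {
    stop_validation("the 0% (wildtype control) level must be included")
  }
  n <- length(percent_levels) * replicates
  if (n > 384) stop_validation("design exceeds the 384-well grid")
  grid <- as.vector(t(outer(LETTERS[1:16], 1:24, paste0)))
  lv <- rep(percent_levels, each = replicates)
  rp <- rep(seq_len(replicates), times = length(percent_levels))
  tibble(well = grid[seq_len(n)],
         sample_id = sprintf("mix%g_r%d", lv, rp),
         role = "clone",
         nominal_percent_mut = lv,
         replicate = rp)
}
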