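# Control-anchored genotype calling from two-channel endpoint fluorescence.
#
# Geometry: after NTC subtraction each well is a point (x, y) with x the
# wildtype-channel and y the mutant-channel signal. The polar angle
# atan2(y, x) encodes allelic composition (0 deg = pure wildtype, 90 deg =
# pure mutant, ~45 deg = heterozygous) and the magnitude x + y encodes
# total amplification. Genotype-control wells anchor one angular centroid
# per genotype class; clones are called by standardized angular distance.
# Wells at no-template signal levels are NO_AMP: NHEJ indels near the
# variant abolish allele-specific primer binding, so NHEJ/NHEJ clones do
# not amplify at all, and compound edited/NHEJ clones amplify at roughly
# half the usual magnitude (the half-signal flag).

GENO_CLASSES <- c("wt_wt", "wt_mut", "mut_mut")
CLASS_CALLS <- c(wt_wt = "WT_WT", wt_mut = "WT_MUT", mut_mut = "MUT_MUT")

#' Caller parameters
#'
#' @param ntc_sd_multiplier `k`: the amplification threshold is the mean
#'   raw NTC magnitude plus `k` NTC standard deviations.
#' @param max_angle_z largest standardized angular distance (`angle_z`) at
#'   which a well is still assigned to a genotype class.
#' @param half_signal_ratio fraction of the class median magnitude below
#'   which a classed call is flagged half-signal (compound edited/NHEJ
#'   clones sit near 0.5; the default 0.6 splits 0.5 from 1 with margin).
#' @param min_controls_per_class minimum amplifying control wells required
#'   per genotype class.
#' @param angle_sd_floor floor (degrees) on the per-class angular standard
#'   deviation, so that noise-free control sets keep a usable acceptance
#'   window. The default 0.75 deg keeps a 5% mutant-fraction well (angle
#'   3.0 deg) outside the wildtype window at `max_angle_z = 3`, which is
#'   what makes low-fraction multi-cell wells detectable as INTERMEDIATE.
#' @return object of class `caller_params`.
#' @export
caller_params <- function(ntc_sd_multiplier = 5, max_angle_z = 3,
                          half_signal_ratio = 0.6, min_controls_per_class = 2,
                          angle_sd_floor = 0.75) {
  for (v in c(ntc_sd_multiplier, max_angle_z, half_signal_ratio,
              min_controls_per_class, angle_sd_floor)) {
    if (!is_number(v) || v <= 0) {
      stop_validation("all caller parameters must be strictly positive numbers")
    }
  }
  structure(list(ntc_sd_multiplier = ntc_sd_multiplier,
                 max_angle_z = max_angle_z,
                 half_signal_ratio = half_signal_ratio,
                 min_controls_per_class = min_controls_per_class,
                 angle_sd_floor = angle_sd_floor),
            class = "caller_params")
}

#' Normalize plate readings against the no-template baseline
#'
#' Subtracts the per-channel NTC mean from every well and clamps at zero:
#' `x = max(rfu_wt - mean_ntc_wt, 0)`, `y = max(rfu_mut - mean_ntc_mut, 0)`.
#' `magnitude = x + y`; `angle = atan2(y, x)` in degrees, `NA` when the
#' magnitude is zero. The NTC summary also retains raw NTC magnitude
#' statistics (before subtraction and clamping) for the amplification
#' threshold.
#'
#' @param panel a [plate_panel()] containing at least one `ntc` well.
#' @return list with `readings` (tibble: `sample_id`, `well`, `role`,
#'   `antibody`, `x`, `y`, `magnitude`, `angle`) and `ntc` (list:
#'   `mean_wt`, `sd_wt`, `mean_mut`, `sd_mut`, `mean_magnitude`,
#'   `sd_magnitude`, `n`). Single-NTC panels report sd 0.
#' @export
normalize_readings <- function(panel) {
  stopifnot(inherits(panel, "plate_panel"))
  r <- panel$readings
  ntc <- r[r$role == "ntc", ]
  if (nrow(ntc) == 0) stop_config("panel has no ntc wells; cannot normalize")
  sd0 <- function(v) if (length(v) >= 2) sd(v) else 0
  raw_mag <- ntc$rfu_wt + ntc$rfu_mut
  ntc_summary <- list(
    mean_wt = mean(ntc$rfu_wt), sd_wt = sd0(ntc$rfu_wt),
    mean_mut = mean(ntc$rfu_mut), sd_mut = sd0(ntc$rfu_mut),
    mean_magnitude = mean(raw_mag), sd_magnitude = sd0(raw_mag),
    n = nrow(ntc))
  x <- pmax(r$rfu_wt - ntc_summary$mean_wt, 0)
  y <- pmax(r$rfu_mut - ntc_summary$mean_mut, 0)
  magnitude <- x + y
  angle <- ifelse(magnitude > 0, atan2(y, x) * 180 / pi, NA_real_)
  list(readings = tibble(sample_id = r$sample_id, well = r$well,
                         role = r$role, antibody = r$antibody,
                         x = x, y = y, magnitude = magnitude, angle = angle),
       ntc = ntc_summary)
}

#' Fit the control-anchored cluster model
#'
#' Each genotype class contributes an angular centroid (mean control
#' angle), a dispersion (sample sd, floored at `angle_sd_floor`) and a
#' median magnitude. The amplification threshold is
#' `mean + k * sd` of the raw NTC magnitudes. Centroids must be ordered
#' `wt_wt < wt_mut < mut_mut`; a violation indicates mislabeled controls.
#'
#' @param norm result of [normalize_readings()].
#' @param params a [caller_params()].
#' @return object of class `cluster_model`: tibble `classes` (`class`,
#'   `centroid_angle`, `angle_sd`, `median_magnitude`, `n_controls`),
#'   `amp_threshold`, and the params used.
#' @export
fit_control_clusters <- function(norm, params = caller_params()) {
  stopifnot(inherits(params, "caller_params"))
  amp_threshold <- norm$ntc$mean_magnitude +
    params$ntc_sd_multiplier * norm$ntc$sd_magnitude
  ctrl_role <- paste0("control_", GENO_CLASSES)
  rows <- lapply(seq_along(GENO_CLASSES), function(i) {
    cls <- GENO_CLASSES[i]
    w <- norm$readings[norm$readings$role == ctrl_role[i] &
                         norm$readings$magnitude > amp_threshold, ]
    if (nrow(w) < params$min_controls_per_class) {
      stop_config(sprintf(
        "class %s has %d amplifying control well(s); need at least %d",
        cls, nrow(w), params$min_controls_per_class))
    }
    tibble(class = cls,
           centroid_angle = mean(w$angle),
           angle_sd = max(if (nrow(w) >= 2) sd(w$angle) else 0,
                          params$angle_sd_floor),
           median_magnitude = median(w$magnitude),
           n_controls = nrow(w))
  })
  classes <- bind_rows(rows)
  if (is.unsorted(classes$centroid_angle, strictly = TRUE)) {
    stop_validation(paste0(
      "control centroids are not ordered wt_wt < wt_mut < mut_mut (",
      paste(sprintf("%s=%.2f", classes$class, classes$centroid_angle),
            collapse = ", "), "); check control labels"))
  }
  structure(list(classes = classes, amp_threshold = amp_threshold,
                 params = params),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> amp_threshold =", format(x$amp_threshold, digits = 5), "\n")
  print(as.data.frame(x$classes), row.names = FALSE)
  invisible(x)
}

#' Call genotypes against a fitted cluster model
#'
#' Wells at or below the amplification threshold are `NO_AMP` (the NHEJ /
#' no-template signature). Otherwise the well is assigned to the genotype
#' class with the smallest `angle_z = |angle - centroid| / angle_sd`,
#' provided that distance is within `max_angle_z`; ties break toward the
#' lower-mutant class (conservative: fewer false HDR positives). A classed
#' well whose magnitude falls below `half_signal_ratio` times the class
#' median magnitude is flagged half-signal. Wells within no class window
#' but lying strictly between two adjacent centroids are `INTERMEDIATE`
#' (the mixed-population signature of multi-cell wells); anything else is
#' `AMBIGUOUS`.
#'
#' @param norm result of [normalize_readings()].
#' @param model a [fit_control_clusters()] model.
#' @param params a [caller_params()]; defaults to the params stored in the
#'   model.
#' @param roles roles to call (default `"clone"`).
#' @return tibble with one row per called well: `sample_id`, `well`,
#'   `call`, `half_signal_flag`, `nearest_class`, `angle`, `magnitude`,
#'   `angle_z` (standardized distance to the nearest centroid; `NA` for
#'   `NO_AMP`).
#' @export
call_genotypes <- function(norm, model, params = model$params,
                           roles = "clone") {
  stopifnot(inherits(model, "cluster_model"))
  r <- norm$readings[norm$readings$role %in% roles, ]
  if (nrow(r) == 0) {
    return(tibble(sample_id = character(), well = character(),
                  call = character(), half_signal_flag = logical(),
                  nearest_class = character(), angle = double(),
                  magnitude = double(), angle_z = double()))
  }
  cls <- model$classes
  out <- lapply(seq_len(nrow(r)), function(i) {
    m <- r$magnitude[i]
    a <- r$angle[i]
    if (m <= model$amp_threshold) {
      return(tibble(sample_id = r$sample_id[i], well = r$well[i],
                    call = "NO_AMP", half_signal_flag = FALSE,
                    nearest_class = NA_character_, angle = a,
                    magnitude = m, angle_z = NA_real_))
    }
    z <- abs(a - cls$centroid_angle) / cls$angle_sd
    best <- which.min(z)   # which.min takes the first minimum: lower-mutant
    call <- "AMBIGUOUS"
    half <- FALSE
    if (z[best] <= params$max_angle_z) {
      call <- CLASS_CALLS[[cls$class[best]]]
      half <- m < params$half_signal_ratio * cls$median_magnitude[best]
    } else if ((a > cls$centroid_angle[1] && a < cls$centroid_angle[2]) ||
               (a > cls$centroid_angle[2] && a < cls$centroid_angle[3])) {
      call <- "INTERMEDIATE"
    }
    tibble(sample_id = r$sample_id[i], well = r$well[i], call = call,
           half_signal_flag = half, nearest_class = cls$class[best],
           angle = a, magnitude = m, angle_z = z[best])
  })
  bind_rows(out)
}

#' Rank intermediate wells as multi-cell HDR candidates
#'
#' Returns the `INTERMEDIATE` calls ordered by ascending standardized
#' angular distance to the heterozygous centroid, i.e. most HDR-like
#' first: in a well seeded with several cells, a larger mutant-allele
#' fraction pulls the well's angle toward the heterozygous cluster.
#'
#' @param calls result of [call_genotypes()].
#' @param model the [fit_control_clusters()] model the calls were made
#'   against (supplies the heterozygous centroid).
#' @return tibble of candidate wells with an extra `angle_z_het` column.
#' @export
detect_intermediate_wells <- function(calls, model) {
  stopifnot(inherits(model, "cluster_model"))
  het <- model$classes[model$classes$class == "wt_mut", ]
  cand <- calls[calls$call == "INTERMEDIATE", ]
  cand$angle_z_het <- abs(cand$angle - het$centroid_angle) / het$angle_sd
  arrange(cand, angle_z_het)
}
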