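# Synthetic-data generators: every input the pipeline consumes, with the
# statistical structure the analysis assumes.
#
# Fluorescence model per well: the measured mutant-allele fraction is the
# true fraction plus a spurious background at low fractions plus Gaussian
# noise (clipped to [0, 1]); the total amplification magnitude is the gain
# scaled by the amplifiable-allele fraction with multiplicative noise.
# Channel RFUs add an independent no-template draw per channel, and the
# mutant channel may carry a gain asymmetry e. NHEJ alleles never amplify,
# so an edited/NHEJ clone emits half the magnitude of a fully amplifiable
# clone and an NHEJ/NHEJ clone is indistinguishable from a no-template
# well.

#' Simulator parameters
#'
#' Defaults are the calibrated study conditions used throughout: the
#' fraction-noise sd and background are set so that a 9-level, 4-replicate
#' titration detects 5% but not 2.5% mutant allele at p < 0.001.
#'
#' @param gain expected full-amplification magnitude (arbitrary RFU,
#'   default 2000).
#' @param fraction_noise_sd additive sd on the measured mutant-allele
#'   fraction (default 0.008).
#' @param background_fraction spurious mutant-channel fraction at 0%
#'   mutant (default 0.005).
#' @param magnitude_cv multiplicative (coefficient-of-variation) noise on
#'   the magnitude (default 0.08).
#' @param ntc_mean,ntc_sd per-channel no-template signal (defaults 60, 12).
#' @param channel_efficiency mutant-channel gain multiplier `e`
#'   (default 1).
#' @return object of class `sim_params`.
#' @export
sim_params <- function(gain = 2000, fraction_noise_sd = 0.008,
                       background_fraction = 0.005, magnitude_cv = 0.08,
                       ntc_mean = 60, ntc_sd = 12, channel_efficiency = 1) {
  stopifnot(gain > 0, fraction_noise_sd >= 0, background_fraction >= 0,
            magnitude_cv >= 0, ntc_mean >= 0, ntc_sd >= 0,
            channel_efficiency > 0)
  structure(list(gain = gain, fraction_noise_sd = fraction_noise_sd,
                 background_fraction = background_fraction,
                 magnitude_cv = magnitude_cv, ntc_mean = ntc_mean,
                 ntc_sd = ntc_sd, channel_efficiency = channel_efficiency),
            class = "sim_params")
}

# Vectorized core: raw two-channel RFUs for wells with the given true
# mutant fractions and amplifiable-allele fractions.
sim_rfus <- function(true_frac_mut, amplifiable_frac, params) {
  n <- length(true_frac_mut)
  f <- clip01(true_frac_mut +
                params$background_fraction * (1 - true_frac_mut) +
                rnorm(n, 0, params$fraction_noise_sd))
  m <- pmax(params$gain * amplifiable_frac *
              (1 + rnorm(n, 0, params$magnitude_cv)), 0)
  ntc_mut <- pmax(rnorm(n, params$ntc_mean, params$ntc_sd), 0)
  ntc_wt <- pmax(rnorm(n, params$ntc_mean, params$ntc_sd), 0)
  tibble(rfu_mut = ntc_mut + m * f * params$channel_efficiency,
         rfu_wt = ntc_wt + m * (1 - f))
}

#' Simulate one well reading
#'
#' @param true_frac_mut mutant fraction among amplifiable alleles, in
#'   `[0, 1]`.
#' @param amplifiable_frac fraction of alleles that amplify (NHEJ alleles
#'   do not); 0 for a no-template well.
#' @param params a [sim_params()].
#' @param seed optional integer seed.
#' @return one-row tibble with `rfu_mut`, `rfu_wt`.
#' @export
simulate_reading <- function(true_frac_mut, amplifiable_frac,
                             params = sim_params(), seed = NULL) {
  stopifnot(true_frac_mut >= 0, true_frac_mut <= 1,
            amplifiable_frac >= 0, amplifiable_frac <= 1)
  if (!is.null(seed)) set.seed(seed)
  sim_rfus(true_frac_mut, amplifiable_frac, params)
}

# Wells fill the 384-well grid row-major; runs larger than one plate
# continue on further plates of the same panel.
well_sequence <- function(n, plate = "simplate") {
  grid <- as.vector(t(outer(LETTERS[1:16], 1:24, paste0)))
  i <- seq_len(n) - 1L
  list(plate_id = if (n <= 384) rep(plate, n)
       else paste0(plate, "_", i %/% 384L + 1L),
       well = grid[i %% 384L + 1L])
}

# Standard anchor block: genotype controls + NTCs appended to a panel.
sim_anchor_wells <- function(params, n_controls = 2, n_ntc = 4) {
  truth <- tibble(
    sample_id = c(sprintf("ctrl_wt_wt_%d", seq_len(n_controls)),
                  sprintf("ctrl_wt_mut_%d", seq_len(n_controls)),
                  sprintf("ctrl_mut_mut_%d", seq_len(n_controls)),
                  sprintf("ntc_%d", seq_len(n_ntc))),
    role = rep(c("control_wt_wt", "control_wt_mut", "control_mut_mut", "ntc"),
               c(n_controls, n_controls, n_controls, n_ntc)),
    frac = rep(c(0, 0.5, 1, 0), c(n_controls, n_controls, n_controls, n_ntc)),
    amp = rep(c(1, 1, 1, 0), c(n_controls, n_controls, n_controls, n_ntc)))
  cbind(truth, sim_rfus(truth$frac, truth$amp, params))
}

#' Simulate a clone-screening plate with ground truth
#'
#' Each well is founded by `cells_per_well` cells; every allele of every
#' founding cell is independently HDR, NHEJ or unedited with the given
#' probabilities. Well fluorescence reflects the pooled alleles: the
#' mutant fraction among amplifiable (non-NHEJ) alleles and the
#' amplifiable fraction. Genotype controls and NTCs are appended.
#'
#' @param n_clones clone wells to simulate.
#' @param cells_per_well founding cells per well (1 = single-cell
#'   cloning; 10 = the multi-cell design).
#' @param p_hdr_allele,p_nhej_allele per-allele outcome probabilities
#'   (`p_hdr + p_nhej <= 1`).
#' @param ploidy alleles per cell (default 2).
#' @param params a [sim_params()].
#' @param seed optional integer seed.
#' @param n_controls,n_ntc anchor wells appended per control class / NTCs.
#' @return list: `panel` (a [plate_panel()]) and `truth` (tibble per clone:
#'   allele counts, `frac_mut_amplifiable`, `amplifiable_frac`,
#'   `true_class` in WT_WT/WT_MUT/MUT_MUT/NO_AMP with `half_signal` for
#'   single-cell edited/NHEJ compounds).
#' @export
simulate_clone_screen <- function(n_clones, cells_per_well = 1,
                                  p_hdr_allele = 0.05, p_nhej_allele = 0.1,
                                  ploidy = 2, params = sim_params(),
                                  seed = NULL, n_controls = 2, n_ntc = 4) {
  if (p_hdr_allele < 0 || p_nhej_allele < 0 ||
      p_hdr_allele + p_nhej_allele > 1) {
    stop_validation("p_hdr_allele + p_nhej_allele must lie in [0, 1]")
  }
  stopifnot(is_count(n_clones, 1), is_count(cells_per_well, 1),
            is_count(ploidy, 1))
  if (!is.null(seed)) set.seed(seed)
  n_alleles <- ploidy * cells_per_well
  states <- matrix(
    sample(c("HDR", "NHEJ", "WT"), n_clones * n_alleles, replace = TRUE,
           prob = c(p_hdr_allele, p_nhej_allele,
                    1 - p_hdr_allele - p_nhej_allele)),
    nrow = n_clones)
  n_hdr <- rowSums(states == "HDR")
  n_nhej <- rowSums(states == "NHEJ")
  n_amp <- n_alleles - n_nhej
  frac <- ifelse(n_amp > 0, n_hdr / n_amp, 0)
  amp <- n_amp / n_alleles
  true_class <- ifelse(n_amp == 0, "NO_AMP",
                       ifelse(n_hdr == 0, "WT_WT",
                              ifelse(n_hdr == n_amp, "MUT_MUT", "WT_MUT")))
  truth <- tibble(
    sample_id = sprintf("clone_%04d", seq_len(n_clones)),
    n_alleles = n_alleles, n_hdr = n_hdr, n_nhej = n_nhej,
    frac_mut_amplifiable = frac, amplifiable_frac = amp,
    true_class = true_class,
    half_signal = n_nhej > 0 & n_amp > 0)
  clones <- cbind(truth[, "sample_id"],
                  role = "clone", sim_rfus(frac, amp, params))
  anchors <- sim_anchor_wells(params, n_controls, n_ntc)
  ws <- well_sequence(nrow(clones) + nrow(anchors))
  readings <- tibble(
    plate_id = ws$plate_id,
    well = ws$well,
    sample_id = c(clones$sample_id, anchors$sample_id),
    role = c(clones$role, anchors$role),
    antibody = NA_character_,
    rfu_mut = c(clones$rfu_mut, anchors$rfu_mut),
    rfu_wt = c(clones$rfu_wt, anchors$rfu_wt))
  list(panel = plate_panel(readings, assay_id = "sim_screen"),
       truth = truth)
}

#' Simulate a titration series and measure it through the pipeline
#'
#' Generates replicate wells at each nominal mutant-allele percentage
#' (full amplification), plus input wells at 50% and NTCs; measures each
#' well's mutant fraction through the input-anchored quantitation path
#' ([compute_conversion_factors()] + [allelic_fraction()]).
#'
#' @param levels nominal mutant percentages; must include 0.
#' @param replicates wells per level.
#' @param params a [sim_params()].
#' @param seed optional integer seed.
#' @param n_input,n_ntc input-DNA and no-template wells.
#' @return list: `measurements` (tibble `nominal_percent_mut`, `replicate`,
#'   `frac_mut`, ready for [lod_analysis()]) and `panel`.
#' @export
simulate_titration <- function(levels = c(0, 1, 2.5, 5, 10, 15, 20, 25, 50),
                               replicates = 4, params = sim_params(),
                               seed = NULL, n_input = 2, n_ntc = 4) {
  design <- mixture_series_design(levels, replicates)
  if (!is.null(seed)) set.seed(seed)
  mix <- cbind(design, sim_rfus(design$nominal_percent_mut / 100,
                                rep(1, nrow(design)), params))
  extra <- tibble(
    sample_id = c(sprintf("input_%d", seq_len(n_input)),
                  sprintf("ntc_%d", seq_len(n_ntc))),
    role = rep(c("input_dna", "ntc"), c(n_input, n_ntc)),
    frac = rep(c(0.5, 0), c(n_input, n_ntc)),
    amp = rep(c(1, 0), c(n_input, n_ntc)))
  extra <- cbind(extra, sim_rfus(extra$frac, extra$amp, params))
  n_mix <- nrow(mix)
  ws <- well_sequence(n_mix + nrow(extra), plate = "simtitration")
  readings <- tibble(
    plate_id = ws$plate_id,
    well = ws$well,
    sample_id = c(mix$sample_id, extra$sample_id),
    role = c(mix$role, extra$role),
    antibody = NA_character_,
    rfu_mut = c(mix$rfu_mut, extra$rfu_mut),
    rfu_wt = c(mix$rfu_wt, extra$rfu_wt))
  panel <- plate_panel(readings, assay_id = "sim_titration")
  norm <- normalize_readings(panel)
  inp <- norm$readings[norm$readings$role == "input_dna", ]
  factors <- compute_conversion_factors(inp)
  rd <- norm$readings[norm$readings$role == "clone", ]
  frac <- vapply(seq_len(nrow(rd)),
                 function(i) allelic_fraction(rd[i, ], factors), numeric(1))
  measurements <- tibble(
    nominal_percent_mut = design$nominal_percent_mut,
    replicate = design$replicate,
    frac_mut = frac[match(design$sample_id, rd$sample_id)])
  list(measurements = measurements, panel = panel)
}

#' Simulate a ChIPnQASO plate
#'
#' Heterozygous truth: input wells at a true mutant fraction of 0.5, IP
#' wells at `rho / (rho + 1)` where `rho` is the allelic preference ratio
#' of the precipitated factor, and IgG wells at near-no-template
#' amplification (2% of full). Any channel-gain asymmetry in `params`
#' applies identically to all wells and cancels in quantitation.
#'
#' @param preference_ratio `rho` > 0 (1 = no preference; 2 = the classic
#'   2:1 risk-allele preference).
#' @param n_bio_replicates,technical_duplicates biological replicates and
#'   technical duplicates per biological replicate.
#' @param antibody label for the IP wells.
#' @param params a [sim_params()].
#' @param seed optional integer seed.
#' @param n_ntc no-template wells.
#' @return list: `panel` (a [plate_panel()]) and `truth` (list with
#'   `frac_mut_ip`).
#' @export
simulate_chip <- function(preference_ratio, n_bio_replicates = 3,
                          technical_duplicates = 2, antibody = "TCF7L2",
                          params = sim_params(), seed = NULL, n_ntc = 4) {
  if (!is_number(preference_ratio) || preference_ratio <= 0) {
    stop_validation("preference_ratio must be > 0")
  }
  stopifnot(is_count(n_bio_replicates, 1), is_count(technical_duplicates, 1))
  if (!is.null(seed)) set.seed(seed)
  f_ip <- preference_ratio / (preference_ratio + 1)
  n_rep <- n_bio_replicates * technical_duplicates
  truth <- tibble(
    sample_id = c(rep("het_clone", 3 * n_rep),
                  sprintf("ntc_%d", seq_len(n_ntc))),
    role = rep(c("input_dna", "ip", "igg", "ntc"),
               c(n_rep, n_rep, n_rep, n_ntc)),
    antibody = rep(c(NA_character_, antibody, NA_character_, NA_character_),
                   c(n_rep, n_rep, n_rep, n_ntc)),
    frac = rep(c(0.5, f_ip, 0.5, 0), c(n_rep, n_rep, n_rep, n_ntc)),
    amp = rep(c(1, 1, 0.02, 0), c(n_rep, n_rep, n_rep, n_ntc)))
  sim <- cbind(truth, sim_rfus(truth$frac, truth$amp, params))
  ws <- well_sequence(nrow(sim), plate = "simchip")
  readings <- tibble(
    plate_id = ws$plate_id,
    well = ws$well,
    sample_id = sim$sample_id, role = sim$role, antibody = sim$antibody,
    rfu_mut = sim$rfu_mut, rfu_wt = sim$rfu_wt)
  list(panel = plate_panel(readings, assay_id = "sim_chip"),
       truth = list(frac_mut_ip = f_ip, preference_ratio = preference_ratio))
}

#' Simulate merged amplicon reads with editing outcomes
#'
#' Each read is independently WT, HDR or NHEJ. WT reads are the reference
#' amplicon and HDR reads the expected HDR amplicon; NHEJ reads carry one
#' indel at the cut site, sized from `indel_sizes` (deletions three times
#' as likely as insertions by default). Deletions remove bases immediately
#' 3' of the blunt cut; insertions add random bases at the cut junction.
#'
#' @param assay an [amplicon_assay()].
#' @param p_hdr,p_nhej per-read outcome probabilities (`p_hdr + p_nhej <=
#'   1`).
#' @param n_reads number of reads.
#' @param indel_sizes candidate indel sizes (default 1:10, uniform).
#' @param deletion_prob probability an NHEJ indel is a deletion (default
#'   0.75, i.e. 3:1 deletion:insertion).
#' @param revcomp_fraction fraction of reads emitted reverse-complemented
#'   (default 0).
#' @param seed optional integer seed.
#' @return list: `reads` (named character vector) and `truth` (tibble
#'   `read_id`, `outcome`, `indel_size` signed negative for deletions, 0
#'   otherwise).
#' @export
simulate_amplicon_reads <- function(assay, p_hdr, p_nhej, n_reads,
                                    indel_sizes = 1:10,
                                    deletion_prob = 0.75,
                                    revcomp_fraction = 0, seed = NULL) {
  stopifnot(inherits(assay, "amplicon_assay"))
  if (p_hdr < 0 || p_nhej < 0 || p_hdr + p_nhej > 1) {
    stop_validation("p_hdr + p_nhej must lie in [0, 1]")
  }
  if (any(indel_sizes < 1)) stop_validation("indel sizes must be >= 1")
  stopifnot(is_count(n_reads, 1))
  if (!is.null(seed)) set.seed(seed)
  outcome <- sample(c("HDR", "NHEJ", "WT"), n_reads, replace = TRUE,
                    prob = c(p_hdr, p_nhej, 1 - p_hdr - p_nhej))
  ref <- assay$reference_amplicon
  cut <- assay$cut_site
  reads <- character(n_reads)
  size <- integer(n_reads)
  reads[outcome == "WT"] <- ref
  reads[outcome == "HDR"] <- assay$expected_hdr_amplicon
  for (i in which(outcome == "NHEJ")) {
    s <- if (length(indel_sizes) == 1) indel_sizes else sample(indel_sizes, 1)
    if (runif(1) < deletion_prob) {
      s <- min(s, nchar(ref) - cut)   # deletion cannot run past the end
      reads[i] <- paste0(substr(ref, 1, cut), substr(ref, cut + s + 1, nchar(ref)))
      size[i] <- -s
    } else {
      ins <- paste(sample(c("A", "C", "G", "T"), s, replace = TRUE),
                   collapse = "")
      reads[i] <- paste0(substr(ref, 1, cut), ins,
                         substr(ref, cut + 1, nchar(ref)))
      size[i] <- s
    }
  }
  if (revcomp_fraction > 0) {
    flip <- runif(n_reads) < revcomp_fraction
    reads[flip] <- as.character(reverseComplement(DNAStringSet(reads[flip])))
  }
  ids <- sprintf("read_%06d", seq_len(n_reads))
  list(reads = setNames(reads, ids),
       truth = tibble(read_id = ids, outcome = outcome, indel_size = size))
}
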