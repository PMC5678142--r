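# Shared fixtures, all generated in code.

# Noise-free simulator settings: every stochastic term switched off so
# closed-form geometry holds exactly.
noise_free_params <- function(...) {
  sim_params(fraction_noise_sd = 0, background_fraction = 0,
             magnitude_cv = 0, ntc_sd = 0, ...)
}

# Minimal hand-built panel: 2 NTCs, 2 controls per class, plus any extra
# clone wells given as a data.frame with sample_id / rfu_mut / rfu_wt.
toy_panel <- function(clones = NULL, ntc = 60, gain = 2000) {
  base <- tibble::tibble(
    sample_id = c("ntc1", "ntc2", "ww1", "ww2", "wm1", "wm2", "mm1", "mm2"),
    role = c("ntc", "ntc", "control_wt_wt", "control_wt_wt",
             "control_wt_mut", "control_wt_mut",
             "control_mut_mut", "control_mut_mut"),
    rfu_mut = ntc + gain * c(0, 0, 0, 0, 0.5, 0.5, 1, 1),
    rfu_wt = ntc + gain * c(0, 0, 1, 1, 0.5, 0.5, 0, 0))
  if (!is.null(clones)) {
    clones$role <- "clone"
    base <- rbind(base, clones[, c("sample_id", "role", "rfu_mut", "rfu_wt")])
  }
  n <- nrow(base)
  plate_panel(tibble::tibble(
    plate_id = "toy", well = paste0(LETTERS[1:16][(seq_len(n) - 1) %/% 24 + 1],
                                    (seq_len(n) - 1) %% 24 + 1),
    sample_id = base$sample_id, role = base$role, antibody = NA_character_,
    rfu_mut = base$rfu_mut, rfu_wt = base$rfu_wt))
}

# Fixed 217-bp amplicon assay: seeded random reference, expected HDR
# amplicon = reference with one substitution right of the blunt cut.
toy_assay <- function(trim = 20, nhej_window = 10) {
  set.seed(217)
  ref <- paste(sample(c("A", "C", "G", "T"), 217, replace = TRUE),
               collapse = "")
  cut <- 108L
  hdr <- ref
  old <- substr(ref, cut + 1, cut + 1)
  substr(hdr, cut + 1, cut + 1) <- setdiff(c("A", "C", "G", "T"), old)[1]
  amplicon_assay(ref, hdr, cut_site = cut, trim = trim,
                 nhej_window = nhej_window)
}

# Map generative clone truth to the expected caller output.
expected_call <- function(truth) truth$true_class
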