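# Editing-outcome arithmetic: T7 indel fraction, genotype frequency /
# allelic-efficiency tables, multi-cell allele math, and a minimal
# amplicon-read HDR/NHEJ classifier.

#' T7 endonuclease I indel percentage
#'
#' From the three gel band intensities of a T7 digestion (two cleavage
#' products and the uncut band):
#' `100 * (1 - sqrt(1 - (cut1 + cut2) / (cut1 + cut2 + uncut)))`.
#' The statistic is scale-invariant in the band intensities.
#'
#' @param cut_band1,cut_band2,uncut_band band intensities (>= 0, not all
#'   zero).
#' @return indel percentage in `[0, 100]`.
#' @examples
#' t7_indel_percent(25, 25, 50)  # 29.29%
#' @export
t7_indel_percent <- function(cut_band1, cut_band2, uncut_band) {
  for (b in c(cut_band1, cut_band2, uncut_band)) {
    if (!is_number(b) || b < 0) stop_validation("band intensities must be numbers >= 0")
  }
  total <- cut_band1 + cut_band2 + uncut_band
  if (total == 0) stop_validation("all bands are zero; indel fraction undefined")
  (1 - sqrt(1 - (cut_band1 + cut_band2) / total)) * 100
}

#' Genotype frequency table and allelic efficiency
#'
#' Per-genotype percentages of a clone screen plus the allelic efficiency:
#' the fraction of all screened alleles carrying the precise edit,
#' `(n_wt_mut + ploidy * n_mut_mut) / (ploidy * n_total) * 100`.
#' Display values are rounded half-up to one decimal; unrounded values are
#' retained alongside.
#'
#' @param n_wt_wt,n_wt_mut,n_mut_mut clone counts per genotype.
#' @param ploidy alleles per clone (default 2).
#' @return object of class `genotype_frequency`: `counts`, `n_total`,
#'   `percent` and `percent_exact` (named vectors wt_wt/wt_mut/mut_mut),
#'   `allelic_efficiency` (rounded) and `allelic_efficiency_exact`.
#' @examples
#' frequency_table(42, 4, 2)$allelic_efficiency   # 8.3
#' frequency_table(50, 3, 4)$allelic_efficiency   # 9.6
#' @export
frequency_table <- function(n_wt_wt, n_wt_mut, n_mut_mut, ploidy = 2) {
  for (v in c(n_wt_wt, n_wt_mut, n_mut_mut)) {
    if (!is_count(v)) stop_validation("genotype counts must be non-negative integers")
  }
  if (!is_count(ploidy, min = 1)) stop_validation("ploidy must be an integer >= 1")
  counts <- c(wt_wt = n_wt_wt, wt_mut = n_wt_mut, mut_mut = n_mut_mut)
  n_total <- sum(counts)
  if (n_total < 1) stop_validation("at least one clone is required")
  percent_exact <- counts / n_total * 100
  ae_exact <- (n_wt_mut + ploidy * n_mut_mut) / (n_total * ploidy) * 100
  structure(list(counts = counts, n_total = n_total, ploidy = ploidy,
                 percent = round_half_up(percent_exact, 1),
                 percent_exact = percent_exact,
                 allelic_efficiency = round_half_up(ae_exact, 1),
                 allelic_efficiency_exact = ae_exact),
            class = "genotype_frequency")
}

#' @export
print.genotype_frequency <- function(x, ...) {
  cat(sprintf("<genotype_frequency> %d clones (ploidy %d)\n", x$n_total, x$ploidy))
  cat(sprintf("  WT/WT %d (%.1f%%), WT/Mut %d (%.1f%%), Mut/Mut %d (%.1f%%)\n",
              x$counts["wt_wt"], x$percent["wt_wt"],
              x$counts["wt_mut"], x$percent["wt_mut"],
              x$counts["mut_mut"], x$percent["mut_mut"]))
  cat(sprintf("  allelic efficiency %.1f%%\n", x$allelic_efficiency))
  invisible(x)
}

#' Mutant-allele percentage of a multi-cell well
#'
#' A well seeded with `n_cells` cells contains `ploidy * n_cells` alleles;
#' heterozygous cells contribute one edited allele each and homozygous
#' cells `ploidy`. One heterozygous cell among 10 diploid cells gives 1
#' mutant allele among 19 wildtype alleles = 5%.
#'
#' @param n_cells cells seeded in the well (>= 1).
#' @param n_het_cells,n_hom_cells edited cell counts
#'   (`n_het_cells + n_hom_cells <= n_cells`).
#' @param ploidy alleles per cell (default 2).
#' @return mutant-allele percentage in `[0, 100]`.
#' @examples
#' multiwell_mut_fraction(10, 1, 0)  # 5
#' @export
multiwell_mut_fraction <- function(n_cells, n_het_cells, n_hom_cells,
                                   ploidy = 2) {
  if (!is_count(n_cells, min = 1) || !is_count(n_het_cells) ||
      !is_count(n_hom_cells) || !is_count(ploidy, min = 1)) {
    stop_validation("cell counts must be non-negative integers (n_cells >= 1)")
  }
  if (n_het_cells + n_hom_cells > n_cells) {
    stop_validation("edited cells exceed cells in the well")
  }
  (n_het_cells + ploidy * n_hom_cells) / (n_cells * ploidy) * 100
}

#' Describe an amplicon assay
#'
#' @param reference_amplicon unedited amplicon sequence (A/C/G/T/N).
#' @param expected_hdr_amplicon amplicon sequence carrying the intended
#'   edit.
#' @param cut_site 0-based offset of the blunt cleavage point into the
#'   reference (between bases `cut_site` and `cut_site + 1`).
#' @param trim bases trimmed from each read end before the exact HDR match
#'   (default 20).
#' @param nhej_window bases either side of the cut within which an indel
#'   counts as NHEJ (default 10).
#' @return object of class `amplicon_assay`.
#' @export
amplicon_assay <- function(reference_amplicon, expected_hdr_amplicon,
                           cut_site, trim = 20, nhej_window = 10) {
  for (s in c(reference_amplicon, expected_hdr_amplicon)) {
    if (!is.character(s) || length(s) != 1 || !grepl("^[ACGTN]+$", s)) {
      stop_validation("amplicon sequences must be single strings over A,C,G,T,N")
    }
  }
  if (!is_count(cut_site) || cut_site > nchar(reference_amplicon)) {
    stop_validation("cut_site must be a 0-based offset within the reference")
  }
  if (!is_count(trim) || !is_count(nhej_window)) {
    stop_validation("trim and nhej_window must be non-negative integers")
  }
  structure(list(reference_amplicon = reference_amplicon,
                 expected_hdr_amplicon = expected_hdr_amplicon,
                 cut_site = as.integer(cut_site), trim = as.integer(trim),
                 nhej_window = as.integer(nhej_window)),
            class = "amplicon_assay")
}

#' Read merged amplicon reads from FASTA or FASTQ
#'
#' Base qualities are ignored; only the sequences matter downstream.
#'
#' @param path sequence file; format guessed from the extension
#'   (`.fq`/`.fastq` = FASTQ, otherwise FASTA) unless given.
#' @param format `"fasta"`, `"fastq"` or `NULL` to guess.
#' @return named character vector of reads.
#' @export
read_amplicon_reads <- function(path, format = NULL) {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  seqs <- readDNAStringSet(path, format = format)
  setNames(as.character(seqs), names(seqs))
}

# Indel positions of one read/reference global alignment, in reference
# coordinates. Deletions are the 1-based reference positions absent from
# the read; insertions are the 0-based junction offsets at which extra
# read bases sit.
alignment_indels <- function(pat, sub) {
  p <- strsplit(pat, "")[[1]]
  s <- strsplit(sub, "")[[1]]
  ref_pos <- cumsum(s != "-")          # reference coordinate per column
  del_pos <- ref_pos[p == "-"]
  ins_jct <- unique(ref_pos[s == "-"]) # column carries pos of last ref base
  list(del = del_pos, ins = ins_jct)
}

#' Classify amplicon reads into HDR / NHEJ / WT outcomes
#'
#' Classification order (a read gets exactly one outcome):
#' 1. HDR - the read trimmed by `trim` bases at each end is an exact
#'    substring of the expected HDR amplicon (the reverse complement is
#'    also checked). Exact matching after trimming is deliberately
#'    stringent; it precedes every other rule.
#' 2. Otherwise the read is globally aligned to the reference (match +1,
#'    mismatch -1, gap open -2, gap extend -0.5; better orientation kept):
#'    NHEJ if the alignment has an insertion or deletion overlapping
#'    `cut_site +/- nhej_window`; WT if it has no indel in that window and
#'    at least 98% identity; else UNCLASSIFIED.
#' Reads shorter than `2 * trim + 1` are UNCLASSIFIED and flagged short.
#'
#' @param reads character vector (or `DNAStringSet`) of merged reads;
#'   names become read ids.
#' @param assay an [amplicon_assay()].
#' @param min_identity identity required for a WT call (default 0.98).
#' @return list: `outcomes` tibble (`read_id`, `outcome`, `flag`) and
#'   `summary` tibble of percentages per class (summing to 100).
#' @export
classify_reads <- function(reads, assay, min_identity = 0.98) {
  stopifnot(inherits(assay, "amplicon_assay"))
  ids <- names(reads)
  reads <- as.character(reads)
  if (length(reads) == 0) stop_validation("no reads supplied")
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(reads))
  outcome <- rep(NA_character_, length(reads))
  flag <- rep("", length(reads))

  too_short <- nchar(reads) < 2 * assay$trim + 1
  outcome[too_short] <- "UNCLASSIFIED"
  flag[too_short] <- "short"

  # HDR: exact substring of the expected amplicon after end trimming.
  open <- which(is.na(outcome))
  if (length(open) > 0) {
    trimmed <- substr(reads[open], assay$trim + 1,
                      nchar(reads[open]) - assay$trim)
    rc <- as.character(reverseComplement(DNAStringSet(trimmed)))
    hit <- vapply(seq_along(trimmed), function(i) {
      grepl(trimmed[i], assay$expected_hdr_amplicon, fixed = TRUE) ||
        grepl(rc[i], assay$expected_hdr_amplicon, fixed = TRUE)
    }, logical(1))
    outcome[open[hit]] <- "HDR"
  }

  # Fast path: reads identical to the reference (either orientation) need
  # no alignment - they are WT by construction of the rules below.
  open <- which(is.na(outcome))
  if (length(open) > 0) {
    rc <- as.character(reverseComplement(DNAStringSet(reads[open])))
    exact_wt <- reads[open] == assay$reference_amplicon |
      rc == assay$reference_amplicon
    outcome[open[exact_wt]] <- "WT"
  }

  open <- which(is.na(outcome))
  if (length(open) > 0) {
    win_lo <- assay$cut_site - assay$nhej_window
    win_hi <- assay$cut_site + assay$nhej_window
    mat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                        baseOnly = FALSE)
    ref <- DNAString(assay$reference_amplicon)
    align_set <- function(x) {
      pairwiseAlignment(DNAStringSet(x), ref, type = "global",
                        substitutionMatrix = mat,
                        gapOpening = 2, gapExtension = 0.5)
    }
    fwd <- align_set(reads[open])
    rev <- align_set(as.character(reverseComplement(DNAStringSet(reads[open]))))
    use_rev <- Biostrings::score(rev) > Biostrings::score(fwd)
    for (i in seq_along(open)) {
      aln <- if (use_rev[i]) rev[i] else fwd[i]
      ind <- alignment_indels(as.character(alignedPattern(aln)),
                              as.character(alignedSubject(aln)))
      # deletion overlaps the window if any deleted reference base does;
      # an insertion if its junction offset lies within it
      del_hit <- any(ind$del > win_lo & ind$del <= win_hi)
      ins_hit <- any(ind$ins >= win_lo & ind$ins <= win_hi)
      if (del_hit || ins_hit) {
        outcome[open[i]] <- "NHEJ"
      } else if (pid(aln, type = "PID1") >= min_identity * 100) {
        outcome[open[i]] <- "WT"
      } else {
        outcome[open[i]] <- "UNCLASSIFIED"
      }
    }
  }

  counts <- table(factor(outcome, levels = c("HDR", "NHEJ", "WT",
                                             "UNCLASSIFIED")))
  pct <- as.numeric(counts) / length(reads) * 100
  list(outcomes = tibble(read_id = ids, outcome = outcome, flag = flag),
       summary = tibble(outcome = names(counts), n = as.integer(counts),
                        percent = pct))
}
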