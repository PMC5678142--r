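test_that("t7_indel_percent evaluates the band formula and is scale-invariant", {
  expect_equal(t7_indel_percent(0, 0, 100), 0)
  expect_equal(t7_indel_percent(50, 50, 0), 100)
  expect_equal(t7_indel_percent(25, 25, 50), (1 - sqrt(0.5)) * 100,
               tolerance = 1e-12)
  for (c in c(0.2, 3, 1e4)) {
    expect_equal(t7_indel_percent(25 * c, 25 * c, 50 * c),
                 t7_indel_percent(25, 25, 50))
  }
  expect_error(t7_indel_percent(0, 0, 0), class = "kaspcall_validation_error")
  expect_error(t7_indel_percent(-1, 0, 10), class = "kaspcall_validation_error")
})

test_that("frequency tables reproduce the screen arithmetic", {
  snv <- frequency_table(42, 4, 2)
  expect_equal(snv$allelic_efficiency, 8.3)      # 8 edited of 96 alleles
  expect_equal(unname(snv$percent["wt_wt"]), 87.5)

  del <- frequency_table(50, 3, 4)
  expect_equal(del$allelic_efficiency, 9.6)      # 11 edited of 114 alleles
  expect_equal(unname(del$percent), c(87.7, 5.3, 7.0))
  expect_equal(sum(del$percent), 100, tolerance = 0.1)

  only_hom <- frequency_table(0, 0, 1)
  expect_equal(unname(only_hom$percent["mut_mut"]), 100)
  expect_equal(only_hom$allelic_efficiency, 100)

  expect_equal(frequency_table(10, 0, 0)$allelic_efficiency, 0)
  # display rounding is half-up, not round-half-even
  expect_equal(round_half_up(0.25 * 100 / 3, 1), 8.3)
  expect_equal(round_half_up(2.45, 1), 2.5)
  expect_error(frequency_table(-1, 0, 0), class = "kaspcall_validation_error")
})

test_that("multi-cell allele math matches the plating design", {
  expect_equal(multiwell_mut_fraction(10, 1, 0), 5)   # 1 of 20 alleles
  expect_equal(multiwell_mut_fraction(1, 1, 0), 50)
  expect_equal(multiwell_mut_fraction(10, 0, 0), 0)
  expect_equal(multiwell_mut_fraction(10, 0, 10), 100)
  expect_equal(multiwell_mut_fraction(10, 2, 1, ploidy = 2), 20)
  expect_error(multiwell_mut_fraction(2, 2, 1),
               class = "kaspcall_validation_error")
})

test_that("reads classify by the HDR-first rule set", {
  assay <- toy_assay()
  ref <- assay$reference_amplicon
  hdr <- assay$expected_hdr_amplicon
  cut <- assay$cut_site
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  del9 <- paste0(substr(ref, 1, cut - 4), substr(ref, cut + 6, nchar(ref)))
  far_snp <- ref
  substr(far_snp, 5, 5) <- if (substr(ref, 5, 5) == "A") "C" else "A"
  reads <- c(as_hdr = hdr, as_wt = ref, del9_at_cut = del9,
             hdr_rc = rc(hdr), wt_rc = rc(ref),
             end_mismatch = far_snp, short = substr(ref, 1, 30))
  out <- classify_reads(reads, assay)
  got <- setNames(out$outcomes$outcome, out$outcomes$read_id)
  expect_equal(unname(got["as_hdr"]), "HDR")
  expect_equal(unname(got["hdr_rc"]), "HDR")
  expect_equal(unname(got["as_wt"]), "WT")
  expect_equal(unname(got["wt_rc"]), "WT")
  expect_equal(unname(got["del9_at_cut"]), "NHEJ")
  # one mismatch outside the window, no indel: still WT at 98% identity
  expect_equal(unname(got["end_mismatch"]), "WT")
  expect_equal(unname(got["short"]), "UNCLASSIFIED")
  expect_equal(out$outcomes$flag[out$outcomes$read_id == "short"], "short")
  expect_equal(sum(out$summary$percent), 100)
})

test_that("indels are NHEJ only when they overlap the cut-site window", {
  assay <- toy_assay(nhej_window = 10)
  ref <- assay$reference_amplicon
  cut <- assay$cut_site
  splice <- function(at, size) {
    paste0(substr(ref, 1, at), substr(ref, at + size + 1, nchar(ref)))
  }
  inside <- splice(cut, 3)          # deletion right of the blunt cut
  edge_in <- splice(cut + 9, 3)     # starts inside the +10 window
  outside <- splice(cut + 30, 3)    # well beyond the window
  out <- classify_reads(c(a = inside, b = edge_in, c = outside), assay)
  got <- setNames(out$outcomes$outcome, out$outcomes$read_id)
  expect_equal(unname(got["a"]), "NHEJ")
  expect_equal(unname(got["b"]), "NHEJ")
  # a distal 3-base deletion is not NHEJ-at-cut; 214/217 matches > 98%: WT
  expect_equal(unname(got["c"]), "WT")

  ins <- paste0(substr(ref, 1, cut), "GGGG", substr(ref, cut + 1, nchar(ref)))
  expect_equal(classify_reads(c(i = ins), assay)$outcomes$outcome, "NHEJ")
})

test_that("classification recovers simulated outcome frequencies", {
  assay <- toy_assay()
  sim <- simulate_amplicon_reads(assay, p_hdr = 0.05, p_nhej = 0.165,
                                 n_reads = 4000, seed = 8)
  out <- classify_reads(sim$reads, assay)
  j <- merge(out$outcomes, sim$truth, by = "read_id")
  expect_identical(j$outcome.x, j$outcome.y)  # exact per-read agreement
  for (p in c(HDR = 0.05, NHEJ = 0.165)) {
    cls <- names(which(c(HDR = 0.05, NHEJ = 0.165) == p))
    obs <- out$summary$percent[out$summary$outcome == cls]
    expect_lt(abs(obs - 100 * p), 3 * 100 * sqrt(p * (1 - p) / 4000))
  }
})

test_that("FASTA and FASTQ inputs are accepted, qualities ignored", {
  assay <- toy_assay()
  sim <- simulate_amplicon_reads(assay, 0.5, 0, n_reads = 6, seed = 2)
  fa <- withr::local_tempfile(fileext = ".fasta")
  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(paste0(">", names(sim$reads), "\n", sim$reads), fa)
  writeLines(paste0("@", names(sim$reads), "\n", sim$reads, "\n+\n",
                    vapply(nchar(sim$reads),
                           function(n) strrep("I", n), character(1))), fq)
  expect_equal(read_amplicon_reads(fa), sim$reads)
  expect_equal(read_amplicon_reads(fq), sim$reads)
  expect_identical(classify_reads(read_amplicon_reads(fa), assay)$summary,
                   classify_reads(read_amplicon_reads(fq), assay)$summary)
})

test_that("assay construction validates sequences and offsets", {
  expect_error(amplicon_assay("ACGTX", "ACGT", 2),
               class = "kaspcall_validation_error")
  expect_error(amplicon_assay("ACGT", "ACGT", 9),
               class = "kaspcall_validation_error")
  a <- amplicon_assay("ACGTACGT", "ACGTTCGT", 4, trim = 1, nhej_window = 2)
  expect_s3_class(a, "amplicon_assay")
})
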