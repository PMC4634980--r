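qstr <- function(v) intToUtf8(v + 33L)

test_that("central and neighborhood quality screens exclude weak bases", {
  ref <- strrep("ACGT", 20)
  ## base 10 at q19 in an otherwise q40 read: central threshold fails
  aln <- fake_alignment(substr(ref, 1, 40),
                        qual = qstr(c(rep(40, 9), 19, rep(40, 30))))
  out <- screen_bases(aln, ref)
  expect_false(10 %in% out$ref_pos)
  expect_equal(nrow(out), 39)
  ## base q30 whose 11-base window averages below 15: neighborhood fails
  q <- c(rep(5, 5), 30, rep(5, 5), rep(40, 29))
  aln2 <- fake_alignment(substr(ref, 1, 40), qual = qstr(q))
  out2 <- screen_bases(aln2, ref)
  expect_false(6 %in% out2$ref_pos)
})

test_that("screened base sets equal an exhaustive window-mean recomputation", {
  set.seed(51)
  ref <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  params <- caller_params()
  for (k in 1:8) {
    len <- sample(30:60, 1)
    st <- sample(1:(120 - len), 1)
    q <- sample(2:40, len, TRUE)
    aln <- fake_alignment(substr(ref, st, st + len - 1), ref_start = st,
                          qual = qstr(q))
    got <- screen_bases(aln, ref, params)$read_pos
    want <- which(vapply(seq_len(len), function(i) {
      win <- q[max(1, i - 5):min(len, i + 5)]
      q[i] >= 20 && mean(win) >= 15
    }, logical(1)))
    expect_identical(got, want)
  }
})

test_that("missing qualities are an input error", {
  ref <- strrep("ACGT", 20)
  aln <- fake_alignment(substr(ref, 1, 40))
  aln$qual <- NA_character_
  expect_error(call_variants(aln, ref), class = "sporevar_input_error")
})

## build n reads spanning the whole reference, n_alt of them carrying an
## alternate base at position pos
snv_pileup <- function(ref, pos, alt, n, n_alt) {
  reads <- lapply(seq_len(n), function(i) {
    s <- ref
    if (i <= n_alt) substr(s, pos, pos) <- alt
    fake_alignment(s, read_id = sprintf("r%03d", i))
  })
  do.call(rbind, reads)
}

test_that("frequency is read count over screened coverage", {
  set.seed(61)
  ref <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  substr(ref, 30, 30) <- "C"
  aln <- snv_pileup(ref, 30, "T", 100, 5)
  calls <- call_variants(aln, ref)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "SNV")
  expect_equal(calls$count, 5L)
  expect_equal(calls$coverage, 100L)
  expect_equal(calls$frequency, 5)
})

test_that("coverage and frequency thresholds suppress calls", {
  set.seed(62)
  ref <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  substr(ref, 30, 30) <- "C"
  ## coverage 8 with 50% alt: below min_coverage 10
  expect_equal(nrow(call_variants(snv_pileup(ref, 30, "T", 8, 4), ref)), 0)
  ## 0.5% at coverage 1000: below min frequency 1%
  calls <- call_variants(snv_pileup(ref, 30, "T", 1000, 5), ref)
  expect_equal(nrow(calls), 0)
  ## 1% exactly is callable
  calls2 <- call_variants(snv_pileup(ref, 30, "T", 1000, 10), ref)
  expect_equal(calls2$frequency, 1)
})

## reads carrying a 1-bp deletion of ref position pos+1, as CIGAR
del_pileup <- function(ref, anchor, n, n_del) {
  L <- nchar(ref)
  reads <- lapply(seq_len(n), function(i) {
    if (i <= n_del) {
      s <- paste0(substr(ref, 1, anchor), substring(ref, anchor + 2))
      fake_alignment(s, cigar = sprintf("%dM1D%dM", anchor, L - anchor - 1),
                     read_id = sprintf("r%03d", i))
    } else {
      fake_alignment(ref, read_id = sprintf("r%03d", i))
    }
  })
  do.call(rbind, reads)
}

test_that("pyro filter removes low-frequency homopolymer indels only", {
  set.seed(63)
  base <- sample(c("A", "C", "G", "T"), 60, TRUE)
  base[25:28] <- "A"; base[24] <- "C"; base[29] <- "G"
  ref <- paste(base, collapse = "")
  ## deletion inside the AAAA run at 2%: removed as pyro error
  calls <- call_variants(del_pileup(ref, 25, 500, 10), ref)
  expect_equal(nrow(calls), 0)
  flt <- call_variants(del_pileup(ref, 25, 500, 10), ref,
                       include_filtered = TRUE)
  expect_equal(flt$filter, "pyro_error")
  expect_equal(flt$type, "Del")
  ## same deletion at 85%: retained
  calls2 <- call_variants(del_pileup(ref, 25, 400, 340), ref)
  expect_equal(nrow(calls2), 1)
  expect_equal(calls2$type, "Del")
  expect_gt(calls2$frequency, 80)
})

test_that("pyro filter leaves non-homopolymer indels alone", {
  set.seed(64)
  base <- sample(c("A", "C", "G", "T"), 60, TRUE)
  base[24:29] <- c("C", "A", "G", "T", "C", "G")  # no run >= 3
  ref <- paste(base, collapse = "")
  calls <- call_variants(del_pileup(ref, 25, 500, 10), ref)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "Del")
  expect_equal(calls$count, 10L)
})

## two adjacent SNVs carried by either the same or disjoint read subsets
mnv_pileup <- function(ref, pos, linked, n = 200, n_alt = 20) {
  reads <- lapply(seq_len(n), function(i) {
    s <- ref
    if (linked) {
      if (i <= n_alt) {
        substr(s, pos, pos) <- "T"; substr(s, pos + 1, pos + 1) <- "G"
      }
    } else {
      if (i <= n_alt) substr(s, pos, pos) <- "T"
      if (i > n - n_alt) substr(s, pos + 1, pos + 1) <- "G"
    }
    fake_alignment(s, read_id = sprintf("r%03d", i))
  })
  do.call(rbind, reads)
}

test_that("adjacent SNVs merge into an MNV only when they co-occur", {
  set.seed(65)
  ref <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  substr(ref, 30, 31) <- "CA"
  linked <- call_variants(mnv_pileup(ref, 30, linked = TRUE), ref)
  expect_equal(nrow(linked), 1)
  expect_equal(linked$type, "MNV")
  expect_equal(linked$ref, "CA")
  expect_equal(linked$alt, "TG")
  expect_equal(linked$count, 20L)
  unlinked <- call_variants(mnv_pileup(ref, 30, linked = FALSE), ref)
  expect_equal(nrow(unlinked), 2)
  expect_setequal(unlinked$type, c("SNV", "SNV"))
})

test_that("no emitted call violates the caller thresholds", {
  ## noisy simulation with the default error model
  p <- make_panel(reference_length = 600, seed = 71)
  params <- caller_params()
  for (sp in p$spores$spore_id[c(1, 5)]) {
    reads <- trim_reads(simulate_reads(p, sp,
                                       read_sim_config(400, seed = 72)))
    mr <- map_all(reads, p$reference, mapping_params(seed = 73))
    calls <- call_variants(mr, params = params)
    if (nrow(calls) == 0) next
    expect_true(all(calls$coverage >= params$min_coverage))
    expect_true(all(calls$frequency >= params$min_variant_frequency))
    expect_true(all(calls$frequency <= 100))
    expect_true(all(calls$count <= calls$coverage))
    ## frequency conservation: frequency * coverage / 100 recovers count
    expect_equal(round(calls$frequency * calls$coverage / 100), calls$count)
    ## surviving homopolymer indels are at or above the pyro cutoff
    hp <- sporevar:::.homopolymer_runs(p$reference)
    for (i in which(calls$type %in% c("Ins", "Del"))) {
      ev <- if (calls$type[i] == "Ins") substring(calls$alt[i], 2) else
        substring(calls$ref[i], 2)
      uch <- unique(strsplit(ev, "")[[1]])
      if (length(uch) != 1) next
      r <- hp[hp$start <= calls$pos[i] + 1 & hp$end >= calls$pos[i] + 1, ]
      if (nrow(r) && r$base == uch && r$length >= 3) {
        expect_gte(calls$frequency[i], 80)
      }
    }
  }
})

test_that("raising the frequency threshold never adds calls", {
  p <- make_panel(reference_length = 600, seed = 81)
  reads <- trim_reads(simulate_reads(p, p$spores$spore_id[2],
                                     read_sim_config(400, seed = 82)))
  mr <- map_all(reads, p$reference, mapping_params(seed = 83))
  n <- vapply(c(1, 2, 5, 20), function(f)
    nrow(call_variants(mr, params = caller_params(
      min_variant_frequency = f))), numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("MNV constituents never appear alongside the merged call", {
  set.seed(66)
  ref <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  substr(ref, 30, 31) <- "CA"
  calls <- call_variants(mnv_pileup(ref, 30, linked = TRUE), ref)
  snv_keys <- vkey(calls[calls$type == "SNV", ])
  expect_false(any(c("30 SNV C T", "31 SNV A G") %in% snv_keys))
})

test_that("calls are deterministically ordered", {
  set.seed(67)
  ref <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  substr(ref, 30, 30) <- "C"; substr(ref, 45, 45) <- "G"
  reads <- lapply(1:60, function(i) {
    s <- ref
    if (i <= 10) substr(s, 45, 45) <- "A"
    if (i > 50) substr(s, 30, 30) <- "T"
    if (i > 20 && i <= 30) substr(s, 30, 30) <- "A"
    fake_alignment(s, read_id = sprintf("r%02d", i))
  })
  calls <- call_variants(do.call(rbind, reads), ref)
  expect_equal(calls$pos, sort(calls$pos))
  at30 <- calls$alt[calls$pos == 30]
  expect_identical(at30, sort(at30))
})

test_that("caller_stats averages coverages with empty-set safety", {
  calls <- data.frame(pos = c(1, 2), type = c("SNV", "Del"),
                      ref = c("A", "AT"), alt = c("T", "A"),
                      count = c(1, 1), coverage = c(10, 20),
                      frequency = c(10, 5), filter = "PASS")
  st <- caller_stats(calls)
  expect_equal(st$average_variant_coverage, 15L)
  expect_equal(st$average_snv_coverage, 10L)
  empty <- calls[0, ]
  st0 <- caller_stats(empty)
  expect_true(is.na(st0$average_variant_coverage))
  expect_true(is.na(st0$average_snv_coverage))
})

test_that("published per-spore coverage columns average as printed", {
  vc <- c(5598, 276, 9308, 436, 4847, 3282, 4509, 2861, 3585)
  sc <- c(4714, 226, 8707, 381, 4297, 3028, 3810, 2689, 3485)
  expect_equal(round_half_away(mean(vc)), 3856)
  expect_equal(round_half_away(mean(sc)), 3482)
})

test_that("single-sample VCF output parses with a standard VCF reader", {
  set.seed(68)
  ref <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  substr(ref, 30, 30) <- "C"
  calls <- call_variants(snv_pileup(ref, 30, "T", 50, 10), ref)
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(calls, vcf, ref)
  v <- suppressWarnings(vcfR::read.vcfR(vcf, verbose = FALSE))
  expect_equal(nrow(v@fix), 1)
  expect_equal(unname(as.integer(v@fix[1, "POS"])), 30L)
  expect_equal(unname(v@fix[1, "ALT"]), "T")
  info <- vcfR::extract.info(v, "FREQ")
  expect_equal(as.numeric(info), 20)
})
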