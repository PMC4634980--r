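## minimal call-set constructor for matrix tests
calls_of <- function(...) {
  rows <- list(...)
  d <- do.call(rbind, lapply(rows, function(r) {
    data.frame(pos = r[[1]], type = r[[2]], ref = r[[3]], alt = r[[4]],
               count = 1L, coverage = 100L, frequency = r[[5]],
               filter = "PASS", stringsAsFactors = FALSE)
  }))
  class(d) <- c("variant_calls", "data.frame")
  d
}

test_that("identical keys share a row; disjoint keys get their own", {
  shared <- unify(list(s1 = calls_of(list(10, "SNV", "A", "T", 40)),
                       s2 = calls_of(list(10, "SNV", "A", "T", 60))))
  expect_equal(nrow(shared$freq), 1)
  expect_equal(sum(!is.na(shared$freq)), 2)
  disjoint <- unify(list(s1 = calls_of(list(10, "SNV", "A", "T", 40)),
                         s2 = calls_of(list(20, "SNV", "C", "G", 60))))
  expect_equal(nrow(disjoint$freq), 2)
  expect_equal(rowSums(!is.na(disjoint$freq)), c(1, 1),
               ignore_attr = TRUE)
  ## same position, different alt: distinct rows
  near <- unify(list(s1 = calls_of(list(10, "SNV", "A", "T", 40)),
                     s2 = calls_of(list(10, "SNV", "A", "G", 60))))
  expect_equal(nrow(near$freq), 2)
})

test_that("duplicate keys within one sample are rejected", {
  dup <- calls_of(list(10, "SNV", "A", "T", 40),
                  list(10, "SNV", "A", "T", 50))
  expect_error(unify(list(s1 = dup)), class = "sporevar_input_error")
})

test_that("row count equals a brute-force key union over random call sets", {
  set.seed(91)
  for (k in 1:6) {
    sets <- lapply(1:4, function(s) {
      n <- sample(3:12, 1)
      pos <- sample(1:50, n)
      calls <- do.call(calls_of, lapply(pos, function(p)
        list(p, "SNV", "A", "T", runif(1, 1, 100))))
      calls
    })
    names(sets) <- paste0("s", 1:4)
    mat <- unify(sets)
    manual <- unique(unlist(lapply(sets, vkey)))
    expect_equal(nrow(mat$freq), length(manual))
  }
})

test_that("threshold selections match the worked examples", {
  sets <- list(
    s1 = calls_of(list(10, "SNV", "A", "T", 100), list(30, "SNV", "C", "G", 5)),
    s2 = calls_of(list(10, "SNV", "A", "T", 100)),
    s3 = calls_of(list(10, "SNV", "A", "T", 100)))
  mat <- unify(sets)
  sel0 <- select_by_threshold(mat, 0)
  expect_equal(nrow(sel0$unique_to_one_sample), 1)
  expect_equal(sel0$unique_to_one_sample$pos, 30)
  expect_equal(sel0$unique_to_one_sample$sample, "s1")
  expect_equal(nrow(sel0$common_to_all), 1)
  sel100 <- select_by_threshold(mat, 100)
  expect_equal(sel100$common_to_all$pos, 10)
  expect_equal(nrow(sel100$unique_to_one_sample), 0)
})

test_that("selections equal exhaustive row scans on random matrices", {
  set.seed(92)
  for (k in 1:6) {
    ns <- sample(2:5, 1)
    sets <- lapply(1:ns, function(s) {
      pos <- sample(seq(5, 95, by = 5), sample(4:10, 1))
      do.call(calls_of, lapply(pos, function(p)
        list(p, "SNV", "A", "T", round(runif(1, 1, 100), 1))))
    })
    names(sets) <- paste0("s", 1:ns)
    mat <- unify(sets)
    for (thr in c(0, 30, 100)) {
      sel <- select_by_threshold(mat, thr)
      pres <- !is.na(mat$freq) & mat$freq >= thr
      expect_equal(nrow(sel$unique_to_one_sample), sum(rowSums(pres) == 1))
      expect_equal(nrow(sel$common_to_all), sum(rowSums(pres) == ns))
    }
    ## partition conservation at threshold 0
    pres0 <- !is.na(mat$freq)
    sel0 <- select_by_threshold(mat, 0)
    expect_equal(nrow(sel0$unique_to_one_sample) + sum(rowSums(pres0) >= 2),
                 nrow(mat$freq))
    ## monotonicity: common_to_all shrinks as the threshold rises
    sizes <- vapply(c(0, 25, 50, 100), function(t)
      nrow(select_by_threshold(mat, t)$common_to_all), numeric(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("summary recovers construction and rounds percentages as declared", {
  ## 6 spores in 2 isolates; engineered presence patterns
  g <- setNames(rep(c("I1", "I2"), each = 3), paste0("s", 1:6))
  sets <- list(
    s1 = calls_of(list(5, "SNV", "A", "T", 50), list(10, "SNV", "C", "G", 10),
                  list(15, "Del", "CT", "C", 20)),
    s2 = calls_of(list(5, "SNV", "A", "T", 50), list(10, "SNV", "C", "G", 30)),
    s3 = calls_of(list(5, "SNV", "A", "T", 50), list(10, "SNV", "C", "G", 40)),
    s4 = calls_of(list(5, "SNV", "A", "T", 50), list(20, "Ins", "A", "AG", 90)),
    s5 = calls_of(list(5, "SNV", "A", "T", 50), list(20, "Ins", "A", "AG", 90)),
    s6 = calls_of(list(5, "SNV", "A", "T", 50), list(20, "Ins", "A", "AG", 90)))
  mat <- unify(sets, g)
  s <- summarize_comparison(mat)
  expect_equal(s$total_variants, 4)
  expect_equal(s$total_snvs, 2)
  expect_equal(s$n_shared_by_all, 1)
  i1 <- s$per_isolate[s$per_isolate$isolate == "I1", ]
  expect_equal(i1$total, 3)       # rows 5 (shared), 10 and 15
  expect_equal(i1$exclusive, 2)   # rows 10 and 15
  expect_equal(i1$exclusive_pct, 50L)
  i2 <- s$per_isolate[s$per_isolate$isolate == "I2", ]
  expect_equal(i2$exclusive, 1)
  expect_equal(i2$exclusive_pct, 25L)
  ## spore exclusives: only s1 holds a singleton row (pos 15)
  expect_equal(s$per_spore$exclusive, c(1, 0, 0, 0, 0, 0))
})

test_that("per-region tallies follow the gene model", {
  m <- toy_gene_model(exon_len = c(30L, 30L), intron_len = 12L, seed = 9)
  ## exon1 1..30, intron 31..42, exon2 43..72
  g <- setNames("I1", "s1")
  sets <- list(s1 = calls_of(list(10, "SNV", substr(m$sequence, 10, 10),
                                  "A", 50),
                             list(35, "SNV", substr(m$sequence, 35, 35),
                                  "A", 50)))
  ## patch alt so it differs from ref
  sets$s1$alt <- ifelse(sets$s1$alt == sets$s1$ref, "C", sets$s1$alt)
  s <- summarize_comparison(unify(sets, g), m)
  expect_setequal(s$per_region$region, c("exon_1", "intron_1"))
  expect_equal(s$per_region$n_variants, c(1, 1))
})

test_that("frequency histogram bins as specified", {
  sets <- list(s1 = calls_of(list(5, "SNV", "A", "T", 1),
                             list(10, "SNV", "A", "T", 50),
                             list(15, "SNV", "A", "T", 99)),
               s2 = calls_of(list(5, "SNV", "A", "T", 30)))
  mat <- unify(sets)
  h <- freq_histogram(mat, "s1")
  expect_equal(unname(h), c(1, 0, 0, 1, 0, 1))
  expect_equal(sum(h), 3)
  ## spore with no calls at all
  sets2 <- c(sets, list(s3 = calls_of(list(5, "SNV", "A", "T", 1))[0, ]))
  ## an all-empty sample cannot enter unify (no rows), so test the empty
  ## bin path through a sample whose rows are all absent cells
  h2 <- freq_histogram(mat, "s2")
  expect_equal(sum(h2), 1)
  ## randomized frequencies against brute-force binning
  set.seed(93)
  f <- round(runif(40, 0.5, 100), 2)
  sets3 <- list(sx = do.call(calls_of, lapply(seq_along(f), function(i)
    list(i * 2, "SNV", "A", "T", f[i]))))
  h3 <- freq_histogram(unify(sets3), "sx")
  manual <- c(sum(f < 2), sum(f >= 2 & f < 20), sum(f >= 20 & f < 40),
              sum(f >= 40 & f < 60), sum(f >= 60 & f < 80), sum(f >= 80))
  expect_equal(unname(h3), manual)
})

test_that("SNV tracks average over the isolate's called spores", {
  g <- setNames(c("I1", "I1", "I2"), c("s1", "s2", "s3"))
  sets <- list(
    s1 = calls_of(list(10, "SNV", "A", "T", 40), list(20, "SNV", "C", "G", 20)),
    s2 = calls_of(list(20, "SNV", "C", "G", 40)),
    s3 = calls_of(list(10, "SNV", "A", "T", 90)))
  mat <- unify(sets, g)
  trk <- snv_track(mat, "I1")
  expect_equal(trk$mean_frequency[trk$pos == 10], 40)  # called in s1 only
  expect_equal(trk$mean_frequency[trk$pos == 20], 30)  # mean of 20 and 40
  trk2 <- snv_track(mat, "I2")
  expect_equal(trk2$pos, 10)
  expect_equal(trk2$mean_frequency, 90)
  ## non-SNV rows never enter the track
  sets$s1 <- rbind(sets$s1, calls_of(list(30, "Del", "AT", "A", 70)))
  trk3 <- snv_track(unify(sets, g), "I1")
  expect_false(30 %in% trk3$pos)
})

test_that("matrix TSV and merged VCF exports are written and consistent", {
  g <- setNames(c("I1", "I2"), c("s1", "s2"))
  sets <- list(s1 = calls_of(list(10, "SNV", "A", "T", 40)),
               s2 = calls_of(list(10, "SNV", "A", "T", 70),
                             list(20, "Ins", "C", "CG", 15)))
  mat <- unify(sets, g)
  tsv <- tempfile(fileext = ".tsv")
  write_matrix_tsv(mat, tsv)
  back <- read.delim(tsv, check.names = FALSE)
  expect_equal(nrow(back), 2)
  expect_equal(back$s1, c(40, NA))
  vcf <- tempfile(fileext = ".vcf")
  write_merged_vcf(mat, vcf, strrep("ACGT", 10))
  lines <- readLines(vcf)
  expect_equal(sum(!startsWith(lines, "#")), 2)
  expect_match(lines[length(lines) - 1], "FR\t40\t70")
})
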