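test_that("panel allocation arithmetic matches the contract", {
  p <- make_panel(reference_length = 200, n_isolates = 3,
                  n_spores_per_isolate = 3, n_shared = 2,
                  n_isolate_unique = 1, n_spore_unique = 1,
                  frequency_sampler = function(n) rep(0.5, n), seed = 7,
                  min_spacing = 3, margin = 10)
  expect_equal(nrow(p$truth), 2 + 3 + 9)
  expect_equal(sum(p$truth$scope == "shared_all"), 2)
  expect_equal(sum(p$truth$scope == "isolate_unique"), 3)
  expect_equal(sum(p$truth$scope == "spore_unique"), 9)
  expect_equal(p$truth$nuclear_frequency, rep(0.5, 14))
})

test_that("all-shared panels give identical expected sets per spore", {
  p <- make_panel(reference_length = 300, n_shared = 6,
                  n_isolate_unique = 0, n_spore_unique = 0, seed = 3)
  sets <- lapply(p$spores$spore_id,
                 function(s) sort(expected_variants(p, s)$variant_id))
  for (s in sets[-1]) expect_identical(s, sets[[1]])
})

test_that("scope expansion equals a brute-force enumeration", {
  p <- make_panel(reference_length = 600, n_isolates = 2,
                  n_spores_per_isolate = 4, n_shared = 3,
                  n_isolate_unique = 2, n_spore_unique = 1, seed = 11)
  for (i in seq_len(nrow(p$spores))) {
    sp <- p$spores$spore_id[i]; iso <- p$spores$isolate[i]
    manual <- character(0)
    for (k in seq_len(nrow(p$truth))) {
      t <- p$truth[k, ]
      hit <- switch(t$scope,
                    shared_all = TRUE,
                    isolate_unique = identical(t$scope_id, iso),
                    spore_unique = identical(t$scope_id, sp))
      if (hit) manual <- c(manual, t$variant_id)
    }
    expect_setequal(expected_variants(p, sp)$variant_id, manual)
  }
  ## truth conservation: union of expected sets is exactly the truth list
  all_ids <- unlist(lapply(p$spores$spore_id,
                           function(s) expected_variants(p, s)$variant_id))
  expect_setequal(unique(all_ids), p$truth$variant_id)
})

test_that("infeasible variant counts raise a capacity error", {
  expect_error(make_panel(reference_length = 60, n_shared = 40, seed = 1),
               class = "sporevar_capacity_error")
})

test_that("truth variants respect placement and representation rules", {
  for (seed in c(2, 13, 77)) {
    p <- make_panel(reference_length = 500, n_shared = 6,
                    n_isolate_unique = 3, n_spore_unique = 1, seed = seed)
    t <- p$truth
    expect_false(anyDuplicated(t$pos) > 0)
    d <- diff(sort(t$pos))
    expect_true(all(d >= 6))
    ## ref alleles match the reference
    for (k in seq_len(nrow(t))) {
      expect_identical(substr(p$reference, t$pos[k],
                              t$pos[k] + nchar(t$ref[k]) - 1L), t$ref[k])
    }
    ## mixture weights per spore sum to 1
    for (pool in p$pools) expect_equal(sum(pool$weight), 1)
  }
})

test_that("panels and read sets are deterministic under their seeds", {
  p1 <- make_panel(reference_length = 600, seed = 5)
  p2 <- make_panel(reference_length = 600, seed = 5)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$reference, p2$reference)
  cfg <- read_sim_config(50, seed = 9)
  f1 <- tempfile(); f2 <- tempfile()
  simulate_reads(p1, p1$spores$spore_id[1], cfg, fastq_path = f1)
  simulate_reads(p2, p2$spores$spore_id[1], cfg, fastq_path = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("error-free reads are exact substrings of their source haplotype", {
  p <- make_panel(reference_length = 600, seed = 21)
  sp <- p$spores$spore_id[4]
  reads <- simulate_reads(p, sp, error_free_config(80, seed = 2))
  pool <- p$pools[[sp]]
  for (i in seq_len(nrow(reads))) {
    hs <- pool$seq[match(reads$hap[i], pool$hap_id)]
    s <- if (reads$strand[i] == "-")
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(reads$seq[i]))) else reads$seq[i]
    expect_true(grepl(s, hs, fixed = TRUE))
  }
})

test_that("FASTQ output round-trips through a standard reader", {
  p <- make_panel(reference_length = 600, seed = 5)
  sp <- p$spores$spore_id[1]
  reads <- simulate_reads(p, sp, read_sim_config(40, seed = 4))
  fq <- tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_identical(back$id, reads$id)
  expect_identical(back$seq, reads$seq)
  expect_identical(back$qual, reads$qual)
  expect_identical(back$hap, reads$hap)
  expect_identical(back$start, reads$start)
})

test_that("observed alt fraction follows the binomial at the set frequency", {
  ## single spore, one variant at nuclear frequency 0.5; with error-free
  ## reads the carrier fraction among reads covering the site is
  ## Binomial(n, 0.5)
  p <- make_panel(reference_length = 250, n_isolates = 1,
                  n_spores_per_isolate = 1, n_shared = 0,
                  n_isolate_unique = 0, n_spore_unique = 1,
                  frequency_sampler = function(n) rep(0.5, n), seed = 17,
                  type_weights = c(SNV = 1), margin = 60)
  sp <- p$spores$spore_id[1]
  v <- p$truth[1, ]
  reads <- simulate_reads(p, sp, error_free_config(4000, seed = 8,
                                                   read_length_mean = 120,
                                                   read_length_sd = 0))
  pool <- p$pools[[sp]]
  carrier <- vapply(pool$variants, function(ids) v$variant_id %in% ids,
                    logical(1))
  covers <- reads$start <= v$pos & reads$start + 119 >= v$pos
  ## carrier haplotypes are shorter/longer only by indels; SNV-only panel
  ## keeps coordinates identical
  n <- sum(covers)
  x <- sum(covers & carrier[match(reads$hap, pool$hap_id)])
  bounds <- qbinom(c(0.0005, 0.9995), n, 0.5)
  expect_gte(x, bounds[1])
  expect_lte(x, bounds[2])
})

test_that("homopolymer indel errors stay inside qualifying runs", {
  ref <- paste0(strrep("ACGT", 20), strrep("A", 8), strrep("CTGA", 20),
                strrep("T", 5), strrep("GACT", 15))
  p <- make_panel(reference = ref, n_isolates = 1, n_spores_per_isolate = 1,
                  n_shared = 1, n_isolate_unique = 0, n_spore_unique = 0,
                  seed = 3, type_weights = c(SNV = 1))
  cfg <- read_sim_config(300, seed = 6, substitution_errors = FALSE,
                         homopolymer_indel_rate = 0.15,
                         homopolymer_min_run = 3)
  reads <- simulate_reads(p, p$spores$spore_id[1], cfg)
  ev <- attr(reads, "hp_events")
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$run_length >= 3))
})

test_that("degenerate configurations are rejected", {
  expect_error(read_sim_config(0), class = "sporevar_config_error")
  expect_error(read_sim_config(10, homopolymer_indel_rate = 1.5),
               class = "sporevar_config_error")
})

test_that("truth exports are written and parseable", {
  p <- make_panel(reference_length = 600, seed = 5)
  tsv <- tempfile(fileext = ".tsv"); vcf <- tempfile(fileext = ".vcf")
  write_truth(p, tsv, vcf)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(p$truth))
  vl <- readLines(vcf)
  expect_true(startsWith(vl[1], "##fileformat=VCF"))
  expect_equal(sum(!startsWith(vl, "#")), nrow(p$truth))
})
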