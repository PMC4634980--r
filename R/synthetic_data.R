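#' Default nuclear-frequency sampler
#'
#' Mixture emulating the observed within-spore frequency spectrum: most
#' variants sit in a low band (0.5-20% of nuclei), with a minority of
#' near-fixed variants (80-100%).
#'
#' @param n number of frequencies to draw.
#' @param p_low probability of drawing from the low band.
#' @return numeric vector of frequencies in (0, 1].
#' @export
default_frequency_sampler <- function(n, p_low = 0.75) {
  low <- runif(n, 0.005, 0.20)
  high <- runif(n, 0.80, 1.00)
  ifelse(runif(n) < p_low, low, high)
}

## is an indel event "clean" at this reference context: left-aligned as-is and
## outside any homopolymer run >= min_run (so the pyro filter cannot touch it)
.indel_context_ok <- function(kind, pos, allele, reference, min_run = 3L) {
  runs <- .homopolymer_runs(reference)
  run_at <- function(p) runs[runs$start <= p & runs$end >= p, , drop = FALSE]
  if (kind == "Ins") {
    la <- .left_align_ins(pos, allele, reference)
    if (la$pos != pos) return(FALSE)
    ## inserted bases sharing identity with the anchor or following base
    ## admit split/shifted equal-cost representations, so the key would not
    ## be representation-stable; require full distinctness from the context
    chars <- strsplit(allele, "", fixed = TRUE)[[1]]
    ctx <- c(substr(reference, pos, pos),
             substr(reference, pos + 1L, pos + 1L))
    if (any(chars %in% ctx)) return(FALSE)
    if (length(unique(chars)) == 1L) {
      r <- run_at(pos + 1L)
      if (nrow(r) && r$base == chars[1] &&
          r$length + nchar(allele) >= min_run) return(FALSE)
    }
    return(TRUE)
  }
  ## Del: allele = deleted reference substring at pos+1 .. pos+len.
  ## Require the whole window (anchor, deleted bases, following base) to be
  ## pairwise distinct: repeats in the window admit equal-cost alternative
  ## decompositions (e.g. two split 1-bp deletions), so the event would not
  ## be representation-stable across aligners.
  len <- nchar(allele)
  win <- strsplit(substr(reference, pos, pos + len + 1L), "",
                  fixed = TRUE)[[1]]
  if (anyDuplicated(win)) return(FALSE)
  if (.left_align_del(pos, len, reference) != pos) return(FALSE)
  for (p in (pos + 1L):(pos + len)) {
    r <- run_at(p)
    if (nrow(r) && r$length >= min_run) return(FALSE)
  }
  TRUE
}

## draw alleles for one variant at pos; falls back to SNV when the local
## context cannot host a clean indel
.draw_variant <- function(type, pos, reference) {
  bases <- c("A", "C", "G", "T")
  refc <- function(p) substr(reference, p, p)
  other <- function(b) sample(setdiff(bases, b), 1L)
  if (type == "MNV") {
    r <- paste0(refc(pos), refc(pos + 1L))
    a <- paste0(other(refc(pos)), other(refc(pos + 1L)))
    return(list(pos = pos, type = "MNV", ref = r, alt = a))
  }
  if (type == "Ins") {
    for (k in 1:8) {
      ins <- paste(sample(bases, sample(1:2, 1L), replace = TRUE),
                   collapse = "")
      if (.indel_context_ok("Ins", pos, ins, reference)) {
        key <- .ins_key(pos, ins, reference)
        return(list(pos = key$pos, type = "Ins", ref = key$ref, alt = key$alt))
      }
    }
    type <- "SNV"
  }
  if (type == "Del") {
    len <- sample(1:2, 1L)
    if (.indel_context_ok("Del", pos, substr(reference, pos + 1L, pos + len),
                          reference)) {
      key <- .del_key(pos, len, reference)
      return(list(pos = key$pos, type = "Del", ref = key$ref, alt = key$alt))
    }
    type <- "SNV"
  }
  if (type == "Repl") {
    ## replacement of 2 ref bases by 1: require the local context
    ## (pos-1, pos, pos+1) pairwise distinct so that either decomposition
    ## (mismatch+deletion) stays left-alignment-stable and re-merges to the
    ## same key; choose an alt base distinct from all three
    ctx <- c(refc(pos - 1L), refc(pos), refc(pos + 1L))
    cand <- setdiff(bases, ctx)
    ## the deleted base must not belong to a homopolymer run >= 3, or the
    ## deletion half of the decomposition would be pyro-filtered
    runs <- .homopolymer_runs(reference)
    rlen <- runs$length[runs$start <= pos + 1L & runs$end >= pos + 1L]
    if (pos > 1L && length(unique(ctx)) == 3L && length(cand) == 1L &&
        rlen < 3L) {
      r <- paste0(refc(pos), refc(pos + 1L))
      return(list(pos = pos, type = "Repl", ref = r, alt = cand))
    }
    type <- "SNV"
  }
  list(pos = pos, type = "SNV", ref = refc(pos), alt = other(refc(pos)))
}

#' Build a truth-annotated multi-isolate, multi-spore haplotype panel
#'
#' Allocates variants over three scopes — shared by every spore, unique to
#' one isolate, unique to one spore — at sampled nuclear frequencies, and
#' realises them as a finite mixture of nuclear haplotypes per spore (default
#' 100 "nuclei"), so that linked variants co-occur on reads the way they do
#' in a multinucleate spore. Nuclear frequencies are snapped to the
#' `1/n_nuclei` grid (minimum one nucleus), so the recorded
#' `nuclear_frequency` is exact, not approximate.
#'
#' Variant positions are drawn without replacement, kept `min_spacing` bases
#' apart (so distinct truth variants are never merged into one MNV/Repl by a
#' caller) and at least `margin` bases from the reference ends (where
#' uniformly placed read windows leave thin coverage). Truth indels are
#' placed only in contexts where they are left-alignment-stable and outside
#' homopolymer runs of length >= 3; contexts that cannot host a clean indel
#' fall back to an SNV.
#'
#' @param reference_length reference length used when `reference` is NULL;
#'   the default mirrors a 1209 bp amplicon.
#' @param n_isolates,n_spores_per_isolate panel shape.
#' @param n_shared,n_isolate_unique,n_spore_unique variants shared by all
#'   spores, per-isolate unique, and per-spore unique, respectively.
#' @param frequency_sampler function(n) returning nuclear frequencies in
#'   (0, 1]; see [default_frequency_sampler()].
#' @param seed integer; fully determines the panel.
#' @param reference optional nucleotide string to use as the reference.
#' @param type_weights named sampling weights over SNV/Ins/Del/MNV/Repl.
#' @param margin,min_spacing placement constraints (bases).
#' @param n_nuclei nuclei per spore realising the mixture.
#' @param isolate_ids optional isolate names (default ISO1, ISO2, ...).
#' @return object of class `haplotype_panel` with elements `reference`,
#'   `isolates`, `spores` (data.frame spore_id/isolate), `truth`
#'   (data.frame variant_id/pos/type/ref/alt/scope/scope_id/
#'   nuclear_frequency), `pools` (per-spore haplotype mixtures), `n_nuclei`,
#'   `seed`.
#' @export
make_panel <- function(reference_length = 1209L, n_isolates = 3L,
                       n_spores_per_isolate = 3L, n_shared = 5L,
                       n_isolate_unique = 4L, n_spore_unique = 2L,
                       frequency_sampler = default_frequency_sampler,
                       seed = 1L, reference = NULL,
                       type_weights = c(SNV = 0.4, Ins = 0.2, Del = 0.2,
                                        MNV = 0.1, Repl = 0.1),
                       margin = 25L, min_spacing = 6L, n_nuclei = 100L,
                       isolate_ids = NULL) {
  .with_seed(seed, {
    if (is.null(reference)) {
      .assert(reference_length >= 50L, "reference_length must be >= 50",
              "sporevar_capacity_error")
      reference <- paste(sample(c("A", "C", "G", "T"), reference_length,
                                replace = TRUE), collapse = "")
    } else {
      reference <- toupper(as.character(reference))
      reference_length <- nchar(reference)
      .assert(reference_length >= 50L, "reference must be >= 50 nt",
              "sporevar_capacity_error")
    }
    if (is.null(isolate_ids)) isolate_ids <- paste0("ISO", seq_len(n_isolates))
    .assert(length(isolate_ids) == n_isolates, "need one id per isolate")
    spores <- data.frame(
      spore_id = paste0(rep(isolate_ids, each = n_spores_per_isolate), "_s",
                        rep(seq_len(n_spores_per_isolate), n_isolates)),
      isolate = rep(isolate_ids, each = n_spores_per_isolate),
      stringsAsFactors = FALSE)
    n_spores <- nrow(spores)
    nv <- n_shared + n_isolates * n_isolate_unique + n_spores * n_spore_unique
    .assert(nv >= 1L, "panel must contain at least one variant",
            "sporevar_capacity_error")

    ## greedy spaced placement, away from the reference ends
    lo <- margin + 1L
    hi <- reference_length - margin - 4L
    .assert(hi >= lo, "reference too short for the requested margin",
            "sporevar_capacity_error")
    cand <- sample(lo:hi)
    pos <- integer(0)
    for (p in cand) {
      if (length(pos) == nv) break
      if (all(abs(pos - p) >= min_spacing + 3L)) pos <- c(pos, p)
    }
    .assert(length(pos) == nv,
            sprintf("cannot place %d variants with spacing %d in %d bp",
                    nv, min_spacing, reference_length),
            "sporevar_capacity_error")
    pos <- sort(pos)

    scope <- c(rep("shared_all", n_shared),
               rep("isolate_unique", n_isolates * n_isolate_unique),
               rep("spore_unique", n_spores * n_spore_unique))
    scope_id <- c(rep(NA_character_, n_shared),
                  rep(isolate_ids, each = n_isolate_unique),
                  rep(spores$spore_id, each = n_spore_unique))
    ## shuffle scope over positions so scopes are not position-ordered
    ord <- sample.int(nv)
    scope <- scope[ord]; scope_id <- scope_id[ord]

    types <- sample(names(type_weights), nv, replace = TRUE,
                    prob = type_weights)
    freq <- frequency_sampler(nv)
    .assert(all(freq > 0 & freq <= 1),
            "frequency_sampler must return values in (0, 1]")
    k_nuc <- pmax(1L, as.integer(round(freq * n_nuclei)))

    truth <- vector("list", nv)
    for (i in seq_len(nv)) {
      v <- .draw_variant(types[i], pos[i], reference)
      truth[[i]] <- data.frame(
        variant_id = sprintf("v%03d", i), pos = v$pos, type = v$type,
        ref = v$ref, alt = v$alt, scope = scope[i], scope_id = scope_id[i],
        nuclear_frequency = k_nuc[i] / n_nuclei, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    .assert(!anyDuplicated(paste(truth$pos, truth$type, truth$ref, truth$alt)),
            "variant key collision", "sporevar_capacity_error")

    ## per-spore nuclear pools
    pools <- list()
    for (s in seq_len(n_spores)) {
      sp <- spores$spore_id[s]
      iso <- spores$isolate[s]
      in_scope <- truth$scope == "shared_all" |
        (truth$scope == "isolate_unique" & truth$scope_id == iso) |
        (truth$scope == "spore_unique" & truth$scope_id == sp)
      vt <- truth[in_scope, , drop = FALSE]
      nucleus_sets <- rep(list(character(0)), n_nuclei)
      for (i in seq_len(nrow(vt))) {
        k <- as.integer(round(vt$nuclear_frequency[i] * n_nuclei))
        carriers <- sample.int(n_nuclei, k)
        for (ncl in carriers) {
          nucleus_sets[[ncl]] <- c(nucleus_sets[[ncl]], vt$variant_id[i])
        }
      }
      keys <- vapply(nucleus_sets,
                     function(v) paste(sort(v), collapse = ","), character(1))
      tab <- table(keys)
      hap_sets <- strsplit(names(tab), ",", fixed = TRUE)
      seqs <- vapply(hap_sets, function(ids) {
        ev <- truth[truth$variant_id %in% ids, , drop = FALSE]
        .apply_events(reference, ev)
      }, character(1))
      pools[[sp]] <- list(
        hap_id = paste0(sp, "_h", seq_along(tab)),
        seq = unname(seqs),
        weight = unname(as.numeric(tab)) / n_nuclei,
        variants = hap_sets)
    }

    structure(list(reference = reference, isolates = isolate_ids,
                   spores = spores, truth = truth, pools = pools,
                   n_nuclei = as.integer(n_nuclei), seed = as.integer(seed)),
              class = "haplotype_panel")
  })
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "haplotype_panel: %d bp reference, %d isolate(s) x %d spore(s), %d truth variants\n",
    nchar(x$reference), length(x$isolates), nrow(x$spores), nrow(x$truth)))
  print(table(x$truth$scope))
  invisible(x)
}

#' Variants expected in one spore
#'
#' Expands variant scopes: a spore carries every shared variant, its
#' isolate's unique variants, and its own spore-unique variants.
#'
#' @param panel a [make_panel()] result.
#' @param spore_id spore identifier.
#' @return the rows of `panel$truth` expected in that spore.
#' @export
expected_variants <- function(panel, spore_id) {
  stopifnot(inherits(panel, "haplotype_panel"))
  .assert(spore_id %in% panel$spores$spore_id,
          sprintf("unknown spore '%s'", spore_id))
  iso <- panel$spores$isolate[panel$spores$spore_id == spore_id]
  t <- panel$truth
  t[t$scope == "shared_all" |
      (t$scope == "isolate_unique" & t$scope_id == iso) |
      (t$scope == "spore_unique" & t$scope_id == spore_id), , drop = FALSE]
}

#' Read-simulation configuration
#'
#' Controls one spore's simulated single-end read set. Per-base Phred
#' qualities are drawn from a clamped normal; when `substitution_errors` is
#' TRUE each base is substituted with probability `10^(-Q/10)`, so the
#' emitted quality string is consistent with the injected error process.
#' Homopolymer indel errors emulate pyro-type chemistry: inside each
#' source-sequence run of length L at or above `homopolymer_min_run`, a
#' 1-base insertion or deletion is injected with probability
#' `homopolymer_indel_rate * (L - 1)`.
#'
#' @param n_reads number of reads (> 0).
#' @param read_length_mean,read_length_sd,min_read_length read-length model
#'   (nt); lengths are clamped to `[min_read_length, source length]`.
#' @param quality_mean,quality_sd Phred quality model, clamped to `[2, 40]`.
#' @param substitution_errors inject quality-linked substitutions?
#' @param homopolymer_indel_rate per-run base rate in `[0, 1]`.
#' @param homopolymer_min_run minimum run length hosting indel errors.
#' @param both_strands emit reads from both orientations?
#' @param seed integer; fully determines the read set.
#' @return object of class `read_sim_config`.
#' @export
read_sim_config <- function(n_reads, read_length_mean = 143,
                            read_length_sd = 25, min_read_length = 30L,
                            quality_mean = 28, quality_sd = 6,
                            substitution_errors = TRUE,
                            homopolymer_indel_rate = 0.001,
                            homopolymer_min_run = 3L, both_strands = TRUE,
                            seed = 1L) {
  .assert(is.numeric(n_reads) && n_reads >= 1,
          "n_reads must be a positive integer", "sporevar_config_error")
  .assert(homopolymer_indel_rate >= 0 && homopolymer_indel_rate <= 1,
          "homopolymer_indel_rate must be in [0, 1]", "sporevar_config_error")
  structure(list(n_reads = as.integer(n_reads),
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd,
                 min_read_length = as.integer(min_read_length),
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 substitution_errors = isTRUE(substitution_errors),
                 homopolymer_indel_rate = homopolymer_indel_rate,
                 homopolymer_min_run = as.integer(homopolymer_min_run),
                 both_strands = isTRUE(both_strands),
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Error-free read-simulation configuration
#'
#' Convenience wrapper around [read_sim_config()]: constant Q40 qualities,
#' no substitution errors, no homopolymer indel errors.
#'
#' @inheritParams read_sim_config
#' @param ... further arguments passed to [read_sim_config()].
#' @export
error_free_config <- function(n_reads, ...) {
  read_sim_config(n_reads, quality_mean = 40, quality_sd = 0,
                  substitution_errors = FALSE, homopolymer_indel_rate = 0,
                  ...)
}

#' Simulate single-end reads for one spore
#'
#' Each read is drawn from the spore's nuclear haplotype mixture (so linked
#' variants co-occur), from a uniformly placed window of the chosen
#' haplotype, then passed through the error model of the
#' [read_sim_config()]. Identical seeds give byte-identical FASTQ output.
#'
#' @param panel a [make_panel()] result.
#' @param spore_id spore to simulate.
#' @param config a [read_sim_config()].
#' @param fastq_path optional path; when given, reads are also written as
#'   Sanger Phred+33 FASTQ with the source haplotype id in the description.
#' @return a `read_set` data.frame: `id`, `seq`, `qual` (Phred+33 string),
#'   `hap` (source haplotype id), `start` (window start on the haplotype),
#'   `strand`, `spore`. Injected homopolymer error events are recorded in
#'   `attr(, "hp_events")`.
#' @export
simulate_reads <- function(panel, spore_id, config, fastq_path = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(config, "read_sim_config"))
  .assert(spore_id %in% panel$spores$spore_id,
          sprintf("unknown spore '%s'", spore_id))
  pool <- panel$pools[[spore_id]]
  bases <- c("A", "C", "G", "T")
  .with_seed(config$seed, {
    n <- config$n_reads
    hap_idx <- sample.int(length(pool$seq), n, replace = TRUE,
                          prob = pool$weight)
    ids <- sprintf("%s_read%06d", spore_id, seq_len(n))
    seqs <- quals <- character(n)
    starts <- integer(n)
    strands <- character(n)
    hp_events <- list()
    for (i in seq_len(n)) {
      hs <- pool$seq[hap_idx[i]]
      hl <- nchar(hs)
      len <- as.integer(round(rnorm(1, config$read_length_mean,
                                    config$read_length_sd)))
      len <- max(config$min_read_length, min(len, hl))
      st <- sample.int(hl - len + 1L, 1L)
      s <- substr(hs, st, st + len - 1L)

      ## homopolymer indel errors within source-sequence runs
      if (config$homopolymer_indel_rate > 0) {
        runs <- .homopolymer_runs(s)
        runs <- runs[runs$length >= config$homopolymer_min_run, , drop = FALSE]
        if (nrow(runs)) {
          hit <- runif(nrow(runs)) <
            config$homopolymer_indel_rate * (runs$length - 1)
          for (r in which(hit)) {
            kind <- sample(c("ins", "del"), 1L)
            at <- runs$start[r]
            if (kind == "ins") {
              s <- paste0(substr(s, 1L, at), runs$base[r], substring(s, at + 1L))
            } else {
              s <- paste0(substr(s, 1L, at - 1L), substring(s, at + 1L))
            }
            hp_events[[length(hp_events) + 1L]] <- data.frame(
              read = ids[i], kind = kind, run_start = runs$start[r],
              run_length = runs$length[r], base = runs$base[r],
              stringsAsFactors = FALSE)
          }
        }
      }

      m <- nchar(s)
      q <- as.integer(round(rnorm(m, config$quality_mean, config$quality_sd)))
      q <- pmin(40L, pmax(2L, q))
      if (config$substitution_errors) {
        err <- runif(m) < 10^(-q / 10)
        if (any(err)) {
          ch <- strsplit(s, "", fixed = TRUE)[[1]]
          for (p in which(err)) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
          s <- paste(ch, collapse = "")
        }
      }
      rev <- config$both_strands && runif(1) < 0.5
      if (rev) {
        s <- .revcomp(s)
        q <- rev(q)
      }
      seqs[i] <- s
      quals[i] <- intToUtf8(q + 33L)
      starts[i] <- st
      strands[i] <- if (rev) "-" else "+"
    }
    reads <- data.frame(id = ids, seq = seqs, qual = quals,
                        hap = pool$hap_id[hap_idx], start = starts,
                        strand = strands, spore = spore_id,
                        stringsAsFactors = FALSE)
    class(reads) <- c("read_set", "data.frame")
    attr(reads, "hp_events") <-
      if (length(hp_events)) do.call(rbind, hp_events) else
        data.frame(read = character(0), kind = character(0),
                   run_start = integer(0), run_length = integer(0),
                   base = character(0), stringsAsFactors = FALSE)
    if (!is.null(fastq_path)) write_fastq(reads, fastq_path)
    reads
  })
}

#' Write a read set as FASTQ (Sanger Phred+33)
#'
#' The header carries the truth-tracing description
#' `hap=<id> start=<pos> strand=<+/->`.
#'
#' @param reads a `read_set` from [simulate_reads()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  hdr <- sprintf("@%s hap=%s start=%d strand=%s",
                 reads$id, reads$hap, reads$start, reads$strand)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(hdr, reads$seq, "+", reads$qual)), con,
             sep = "\n")
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ path (Sanger Phred+33).
#' @return a `read_set` data.frame with `id`, `seq`, `qual` and, when
#'   present in the description, `hap`/`start`/`strand` truth fields.
#' @export
read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  full <- names(dna)
  id <- sub("\\s.*$", "", full)
  grab <- function(key) {
    m <- regmatches(full, regexpr(paste0(key, "=[^ ]+"), full))
    out <- rep(NA_character_, length(full))
    hit <- grepl(paste0(key, "="), full)
    out[hit] <- sub(paste0(key, "="), "", m)
    out
  }
  reads <- data.frame(id = id, seq = as.character(dna),
                      qual = as.character(S4Vectors::mcols(dna)$qualities),
                      hap = grab("hap"),
                      start = suppressWarnings(as.integer(grab("start"))),
                      strand = grab("strand"),
                      spore = NA_character_, stringsAsFactors = FALSE)
  class(reads) <- c("read_set", "data.frame")
  reads
}

#' Write a panel's truth set as TSV and/or VCF
#'
#' @param panel a [make_panel()] result.
#' @param tsv_path,vcf_path output paths (either may be NULL).
#' @return invisibly, the written paths.
#' @export
write_truth <- function(panel, tsv_path = NULL, vcf_path = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  out <- character(0)
  if (!is.null(tsv_path)) {
    write.table(panel$truth, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out <- c(out, tsv_path)
  }
  if (!is.null(vcf_path)) {
    t <- panel$truth
    scope <- ifelse(is.na(t$scope_id), t$scope,
                    paste0(t$scope, ":", t$scope_id))
    lines <- c(
      "##fileformat=VCFv4.2",
      sprintf("##contig=<ID=amplicon,length=%d>", nchar(panel$reference)),
      "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type\">",
      "##INFO=<ID=SCOPE,Number=1,Type=String,Description=\"Truth scope\">",
      "##INFO=<ID=NF,Number=1,Type=Float,Description=\"Nuclear frequency\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
      sprintf("amplicon\t%d\t%s\t%s\t%s\t.\tPASS\tTYPE=%s;SCOPE=%s;NF=%s",
              t$pos, t$variant_id, t$ref, t$alt, t$type, scope,
              format(t$nuclear_frequency, trim = TRUE)))
    writeLines(lines, vcf_path)
    out <- c(out, vcf_path)
  }
  invisible(out)
}
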