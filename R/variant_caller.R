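#' Variant-caller parameters
#'
#' Quality-score low-frequency detection thresholds. Defaults are the
#' amplicon setting this package models: minimum coverage 10, minimum
#' variant frequency 1%, neighborhood radius 5 with minimum neighborhood
#' quality 15 and minimum central quality 20, and pyro-error removal of
#' indels inside homopolymer runs of length >= 3 with frequency below 0.8
#' (i.e. 80%).
#'
#' @param min_coverage minimum quality-screened coverage at a site.
#' @param min_variant_frequency minimum frequency in percent, (0, 100].
#' @param neighborhood_radius window half-width (read bases) for the
#'   neighborhood quality screen.
#' @param min_neighborhood_quality minimum mean Phred quality of the
#'   (truncated) window, central base included.
#' @param min_central_quality minimum Phred quality of the base itself.
#' @param pyro_filter_enabled remove homopolymer pyro-error indels?
#' @param homopolymer_min_length minimum reference run length for the
#'   pyro filter.
#' @param pyro_frequency_below indel candidates in qualifying runs with
#'   frequency below this fraction (of 1) are removed.
#' @param mnv_cooccurrence_min minimum fraction of co-carrying reads for
#'   merging adjacent events into MNV/Repl calls.
#' @param read_end_exclusion read bases within this distance of either read
#'   end contribute to neither counts nor coverage. Reads whose window
#'   truncates an indel are systematically re-aligned as mismatches or
#'   shifted gaps at their ends; excluding the outermost bases suppresses
#'   these alignment-boundary artifacts.
#' @param indel_end_exclusion like `read_end_exclusion` but for indel
#'   observations, which is deeper: equal-cost split-gap representations of
#'   a boundary-truncated indel can reach further into the read than
#'   substitution artifacts do.
#' @return object of class `caller_params`.
#' @export
caller_params <- function(min_coverage = 10L, min_variant_frequency = 1,
                          neighborhood_radius = 5L,
                          min_neighborhood_quality = 15,
                          min_central_quality = 20,
                          pyro_filter_enabled = TRUE,
                          homopolymer_min_length = 3L,
                          pyro_frequency_below = 0.8,
                          mnv_cooccurrence_min = 0.5,
                          read_end_exclusion = 5L,
                          indel_end_exclusion = 10L) {
  .assert(min_variant_frequency > 0 && min_variant_frequency <= 100,
          "min_variant_frequency must be in (0, 100]")
  .assert(min_coverage >= 0 && neighborhood_radius >= 0 &&
            min_neighborhood_quality >= 0 && min_central_quality >= 0 &&
            pyro_frequency_below >= 0 && mnv_cooccurrence_min >= 0,
          "thresholds must be non-negative")
  structure(list(min_coverage = as.integer(min_coverage),
                 min_variant_frequency = min_variant_frequency,
                 neighborhood_radius = as.integer(neighborhood_radius),
                 min_neighborhood_quality = min_neighborhood_quality,
                 min_central_quality = min_central_quality,
                 pyro_filter_enabled = isTRUE(pyro_filter_enabled),
                 homopolymer_min_length = as.integer(homopolymer_min_length),
                 pyro_frequency_below = pyro_frequency_below,
                 mnv_cooccurrence_min = mnv_cooccurrence_min,
                 read_end_exclusion = as.integer(read_end_exclusion),
                 indel_end_exclusion = as.integer(indel_end_exclusion)),
            class = "caller_params")
}

## per-base screen of one quality vector: central quality plus truncated
## window mean (central base included)
.screen_mask <- function(q, params) {
  m <- length(q)
  r <- params$neighborhood_radius
  cs <- cumsum(q)
  lo <- pmax(1L, seq_len(m) - r)
  hi <- pmin(m, seq_len(m) + r)
  wmean <- (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
  q >= params$min_central_quality & wmean >= params$min_neighborhood_quality
}

## walk mapped alignments, producing screened observations.
## returns: sub (read, pos, base, read_pos, qual), ins (read, pos, seq),
## del (read, pos, len), coverage (int vector), spans (ref cover per read),
## read_ids
.walk_alignments <- function(aln, reference, params) {
  aln <- aln[aln$mapped, , drop = FALSE]
  ref_len <- nchar(reference)
  n <- nrow(aln)
  sub <- list(); ins <- list(); del <- list()
  span_start <- integer(n); span_end <- integer(n)
  coverage <- integer(ref_len)
  for (i in seq_len(n)) {
    .assert(!is.na(aln$qual[i]) && nchar(aln$qual[i]) == nchar(aln$seq[i]),
            "alignments must carry per-base qualities",
            "sporevar_input_error")
    q <- .qual_ints(aln$qual[i])
    pass <- .screen_mask(q, params)
    ## suppress alignment-boundary artifacts: the outermost read bases are
    ## excluded from counts and coverage alike
    excl <- params$read_end_exclusion %||% 0L
    if (excl > 0L) {
      m <- length(pass)
      drop <- seq_len(m) <= excl | seq_len(m) > m - excl
      pass <- pass & !drop
    }
    chars <- strsplit(aln$seq[i], "", fixed = TRUE)[[1]]
    cg <- .parse_cigar(aln$cigar[i])
    rp <- 1L; fp <- aln$ref_start[i]
    span_start[i] <- fp
    for (k in seq_along(cg$op)) {
      len <- cg$len[k]
      op <- cg$op[k]
      if (op == "S") {
        rp <- rp + len
      } else if (op == "M") {
        rps <- rp:(rp + len - 1L)
        fps <- fp:(fp + len - 1L)
        ok <- pass[rps] & fps >= 1L & fps <= ref_len
        if (any(ok)) {
          coverage[fps[ok]] <- coverage[fps[ok]] + 1L
          sub[[length(sub) + 1L]] <- data.frame(
            read = i, pos = fps[ok], base = chars[rps[ok]],
            read_pos = rps[ok], qual = q[rps[ok]], stringsAsFactors = FALSE)
        }
        rp <- rp + len; fp <- fp + len
      } else if (op == "I") {
        anchor <- fp - 1L
        iex <- params$indel_end_exclusion %||% 0L
        m <- length(pass)
        if (anchor >= 1L && rp > 1L && pass[rp - 1L] &&
            all(pass[rp:(rp + len - 1L)]) &&
            rp - 1L > iex && rp + len - 1L <= m - iex) {
          ins[[length(ins) + 1L]] <- data.frame(
            read = i, pos = anchor,
            seq = paste(chars[rp:(rp + len - 1L)], collapse = ""),
            stringsAsFactors = FALSE)
        }
        rp <- rp + len
      } else if (op == "D") {
        anchor <- fp - 1L
        iex <- params$indel_end_exclusion %||% 0L
        m <- length(pass)
        if (anchor >= 1L && rp > 1L && rp <= m &&
            pass[rp - 1L] && pass[rp] &&
            rp - 1L > iex && rp <= m - iex) {
          del[[length(del) + 1L]] <- data.frame(
            read = i, pos = anchor, len = len, stringsAsFactors = FALSE)
        }
        fp <- fp + len
      }
    }
    span_end[i] <- fp - 1L
  }
  list(
    sub = if (length(sub)) do.call(rbind, sub) else
      data.frame(read = integer(0), pos = integer(0), base = character(0),
                 read_pos = integer(0), qual = integer(0)),
    ins = if (length(ins)) do.call(rbind, ins) else
      data.frame(read = integer(0), pos = integer(0), seq = character(0)),
    del = if (length(del)) do.call(rbind, del) else
      data.frame(read = integer(0), pos = integer(0), len = integer(0)),
    coverage = coverage,
    spans = data.frame(start = span_start, end = span_end),
    read_ids = aln$read_id)
}

#' Quality-screen aligned read bases
#'
#' A read base contributes to the pileup iff its own Phred quality reaches
#' `min_central_quality` and the mean quality of read bases within
#' `neighborhood_radius` positions (window truncated at read ends, central
#' base included) reaches `min_neighborhood_quality`. Screened-out bases
#' contribute to neither allele counts nor coverage.
#'
#' @param alignments a [map_all()] result or its `alignments` data.frame.
#' @param reference reference nucleotide string.
#' @param params a [caller_params()].
#' @return data.frame of surviving base observations: `read_id`,
#'   `read_pos`, `ref_pos`, `base`, `qual`.
#' @export
screen_bases <- function(alignments, reference, params = caller_params()) {
  aln <- if (inherits(alignments, "map_result")) alignments$alignments
    else alignments
  params$read_end_exclusion <- 0L   # pure quality screen, no end exclusion
  w <- .walk_alignments(aln, reference, params)
  data.frame(read_id = w$read_ids[w$sub$read], read_pos = w$sub$read_pos,
             ref_pos = w$sub$pos, base = w$sub$base, qual = w$sub$qual,
             stringsAsFactors = FALSE)
}

.type_rank <- c(SNV = 1L, MNV = 2L, Ins = 3L, Del = 4L, Repl = 5L)

## trim shared leading/trailing bases of a merged ref/alt pair (VCF-style),
## keeping at least an anchored shape
.normalize_pair <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substring(ref, 2L); alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Call low-frequency variants from mapped reads
#'
#' Builds a quality-screened pileup (see [screen_bases()]), then:
#' substitution and left-aligned anchored indel alleles with screened
#' coverage `>= min_coverage` and frequency `>= min_variant_frequency`
#' become candidates; indel candidates inside reference homopolymer runs of
#' length `>= homopolymer_min_length` with frequency below
#' `pyro_frequency_below` are removed as pyro errors; adjacent candidates
#' whose supporting reads co-occur at a fraction
#' `>= mnv_cooccurrence_min` are merged — all-substitution chains into MNVs,
#' mixed substitution/indel chains into replacements (Repl) — with
#' constituent calls suppressed. A merge is cancelled when the merged record
#' itself would violate the coverage or frequency thresholds. Output is
#' sorted by (position, type SNV < MNV < Ins < Del < Repl, alt allele) and
#' fully deterministic.
#'
#' @param alignments a [map_all()] result or its `alignments` data.frame.
#' @param reference reference nucleotide string; when `alignments` is a
#'   `map_result` it defaults to the mapping reference.
#' @param params a [caller_params()].
#' @param include_filtered also return pyro-removed candidates (with
#'   `filter = "pyro_error"`)?
#' @return `variant_calls` data.frame: `pos`, `type`, `ref`, `alt`,
#'   `count`, `coverage`, `frequency` (percent), `filter`, plus a
#'   list-column `read_ids` of supporting reads. The screened coverage
#'   vector is attached as `attr(, "pileup_coverage")`.
#' @export
call_variants <- function(alignments, reference = NULL,
                          params = caller_params(),
                          include_filtered = FALSE) {
  if (inherits(alignments, "map_result")) {
    if (is.null(reference)) reference <- alignments$reference
    alignments <- alignments$alignments
  }
  .assert(!is.null(reference), "reference is required",
          "sporevar_input_error")
  empty <- data.frame(pos = integer(0), type = character(0),
                      ref = character(0), alt = character(0),
                      count = integer(0), coverage = integer(0),
                      frequency = numeric(0), filter = character(0),
                      stringsAsFactors = FALSE)
  empty$read_ids <- list()
  class(empty) <- c("variant_calls", "data.frame")
  if (nrow(alignments) == 0L || !any(alignments$mapped)) return(empty)
  w <- .walk_alignments(alignments, reference, params)
  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  cov <- w$coverage

  cands <- list()
  add_cand <- function(pos, ref, alt, reads) {
    count <- length(unique(reads))
    coverage <- max(cov[pos], count)
    freq <- 100 * count / coverage
    type <- classify_alleles(ref, alt)
    span <- switch(type,
                   SNV = c(pos, pos),
                   MNV = c(pos, pos + nchar(ref) - 1L),
                   Ins = c(pos, pos),
                   Del = c(pos + 1L, pos + nchar(ref) - 1L),
                   Repl = c(pos, pos + nchar(ref) - 1L))
    cands[[length(cands) + 1L]] <<- list(
      pos = pos, type = type, ref = ref, alt = alt, count = count,
      coverage = coverage, frequency = freq, reads = unique(reads),
      span = span, filter = "PASS")
  }

  ## substitution candidates
  if (nrow(w$sub)) {
    alt_obs <- w$sub[w$sub$base != ref_chars[w$sub$pos] &
                       w$sub$base %in% c("A", "C", "G", "T"), , drop = FALSE]
    if (nrow(alt_obs)) {
      grp <- split(alt_obs$read, paste(alt_obs$pos, alt_obs$base))
      for (g in names(grp)) {
        pb <- strsplit(g, " ", fixed = TRUE)[[1]]
        add_cand(as.integer(pb[1]), ref_chars[as.integer(pb[1])], pb[2],
                 grp[[g]])
      }
    }
  }
  ## insertion candidates (left-aligned, anchored)
  if (nrow(w$ins)) {
    keys <- vapply(seq_len(nrow(w$ins)), function(i) {
      k <- .ins_key(w$ins$pos[i], w$ins$seq[i], reference)
      paste(k$pos, k$ref, k$alt, sep = "|")
    }, character(1))
    grp <- split(w$ins$read, keys)
    for (g in names(grp)) {
      k <- strsplit(g, "|", fixed = TRUE)[[1]]
      add_cand(as.integer(k[1]), k[2], k[3], grp[[g]])
    }
  }
  ## deletion candidates (left-aligned, anchored)
  if (nrow(w$del)) {
    keys <- vapply(seq_len(nrow(w$del)), function(i) {
      k <- .del_key(w$del$pos[i], w$del$len[i], reference)
      paste(k$pos, k$ref, k$alt, sep = "|")
    }, character(1))
    grp <- split(w$del$read, keys)
    for (g in names(grp)) {
      k <- strsplit(g, "|", fixed = TRUE)[[1]]
      add_cand(as.integer(k[1]), k[2], k[3], grp[[g]])
    }
  }
  if (length(cands) == 0L) return(empty)

  ## coverage / frequency thresholds
  pass_thresholds <- function(cand) {
    cand$coverage >= params$min_coverage &&
      cand$frequency >= params$min_variant_frequency
  }
  cands <- Filter(pass_thresholds, cands)
  if (length(cands) == 0L) return(empty)

  ## pyro-error filter on indel candidates
  runs <- .homopolymer_runs(reference)
  run_at <- function(p) runs[runs$start <= p & runs$end >= p, , drop = FALSE]
  filtered <- list()
  if (params$pyro_filter_enabled) {
    keep <- logical(length(cands))
    for (i in seq_along(cands)) {
      cand <- cands[[i]]
      keep[i] <- TRUE
      if (!cand$type %in% c("Ins", "Del")) next
      event <- if (cand$type == "Ins") substring(cand$alt, 2L) else
        substring(cand$ref, 2L)
      uch <- unique(strsplit(event, "", fixed = TRUE)[[1]])
      if (length(uch) != 1L) next
      r <- run_at(cand$pos + 1L)
      if (nrow(r) && r$base == uch &&
          r$length >= params$homopolymer_min_length &&
          cand$frequency < 100 * params$pyro_frequency_below) {
        cand$filter <- "pyro_error"
        filtered[[length(filtered) + 1L]] <- cand
        keep[i] <- FALSE
      }
    }
    cands <- cands[keep]
  }

  ## merge adjacent co-occurring candidates into MNV / Repl: build a
  ## co-occurrence graph over span-adjacent candidates and merge each
  ## connected component whose joint support passes the thresholds
  if (length(cands) > 1L) {
    ord <- order(vapply(cands, function(c) c$span[1], numeric(1)),
                 vapply(cands, function(c) c$span[2], numeric(1)))
    cands <- cands[ord]
    spans <- w$spans
    covers <- function(a, b) which(spans$start <= a & spans$end >= b)
    nc <- length(cands)
    parent <- seq_len(nc)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(nc - 1L)) {
      for (j in (i + 1L):nc) {
        si <- cands[[i]]$span; sj <- cands[[j]]$span
        if (sj[1] > si[2] + 1L) break          # sorted: no later adjacency
        both <- intersect(cands[[i]]$reads, cands[[j]]$reads)
        if (length(both) == 0L) next
        denom <- intersect(covers(min(si[1], sj[1]), max(si[2], sj[2])),
                           union(cands[[i]]$reads, cands[[j]]$reads))
        frac <- if (length(denom)) length(both) / length(denom) else 0
        if (frac >= params$mnv_cooccurrence_min) {
          parent[find(i)] <- find(j)
        }
      }
    }
    comp <- vapply(seq_len(nc), find, integer(1))
    merged <- list()
    for (cp in unique(comp)) {
      members <- cands[comp == cp]
      if (length(members) == 1L) {
        merged[[length(merged) + 1L]] <- members[[1]]
        next
      }
      support <- Reduce(intersect, lapply(members, function(c) c$reads))
      lo <- min(vapply(members, function(c) c$span[1], numeric(1)))
      hi <- max(vapply(members, function(c) c$span[2], numeric(1)))
      ## build merged ref/alt by walking the covered slice
      del_pos <- integer(0)
      sub_map <- list(); ins_map <- list()
      ok <- TRUE
      for (cand in members) {
        if (cand$type == "Del") {
          dp <- (cand$pos + 1L):(cand$pos + nchar(cand$ref) - 1L)
          if (any(dp %in% del_pos)) ok <- FALSE
          del_pos <- c(del_pos, dp)
        } else if (cand$type == "Ins") {
          key <- as.character(cand$pos)
          if (!is.null(ins_map[[key]])) ok <- FALSE
          ins_map[[key]] <- substring(cand$alt, 2L)
        } else {
          p <- cand$pos
          for (k in seq_len(nchar(cand$ref))) {
            key <- as.character(p + k - 1L)
            if (!is.null(sub_map[[key]])) ok <- FALSE
            sub_map[[key]] <- substr(cand$alt, k, k)
          }
        }
      }
      rec <- NULL
      if (ok && length(support) > 0L) {
        alt <- character(0)
        for (p in lo:hi) {
          key <- as.character(p)
          if (!(p %in% del_pos)) {
            alt <- c(alt, if (!is.null(sub_map[[key]])) sub_map[[key]] else
              ref_chars[p])
          }
          if (!is.null(ins_map[[key]])) alt <- c(alt, ins_map[[key]])
        }
        norm <- .normalize_pair(lo, paste(ref_chars[lo:hi], collapse = ""),
                                paste(alt, collapse = ""))
        count <- length(support)
        coverage <- min(vapply(members, function(c) c$coverage, numeric(1)))
        rec <- list(pos = norm$pos,
                    type = classify_alleles(norm$ref, norm$alt),
                    ref = norm$ref, alt = norm$alt, count = count,
                    coverage = coverage,
                    frequency = 100 * count / coverage,
                    reads = support, span = c(lo, hi), filter = "PASS")
        if (!pass_thresholds(rec) || rec$ref == rec$alt) rec <- NULL
      }
      if (!is.null(rec)) {
        merged[[length(merged) + 1L]] <- rec
      } else {
        for (cand in members) merged[[length(merged) + 1L]] <- cand
      }
    }
    cands <- merged
  }

  if (include_filtered) cands <- c(cands, filtered)
  out <- data.frame(
    pos = vapply(cands, function(c) as.integer(c$pos), integer(1)),
    type = vapply(cands, function(c) c$type, character(1)),
    ref = vapply(cands, function(c) c$ref, character(1)),
    alt = vapply(cands, function(c) c$alt, character(1)),
    count = vapply(cands, function(c) as.integer(c$count), integer(1)),
    coverage = vapply(cands, function(c) as.integer(c$coverage), integer(1)),
    frequency = vapply(cands, function(c) c$frequency, numeric(1)),
    filter = vapply(cands, function(c) c$filter, character(1)),
    stringsAsFactors = FALSE)
  out$read_ids <- lapply(cands, function(c) w$read_ids[c$reads])
  ord <- order(out$pos, .type_rank[out$type], out$alt)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  attr(out, "pileup_coverage") <- cov
  out
}

#' Coverage statistics over a call set
#'
#' Mean coverage over all calls and over SNV calls only, rounded to the
#' nearest integer (half away from zero). Empty call sets yield `NA`, not
#' zero.
#'
#' @param calls a `variant_calls` data.frame.
#' @return list with `average_variant_coverage` and `average_snv_coverage`.
#' @export
caller_stats <- function(calls) {
  pass <- calls[calls$filter == "PASS", , drop = FALSE]
  snv <- pass[pass$type == "SNV", , drop = FALSE]
  list(
    average_variant_coverage = if (nrow(pass))
      as.integer(round_half_away(mean(pass$coverage))) else NA_integer_,
    average_snv_coverage = if (nrow(snv))
      as.integer(round_half_away(mean(snv$coverage))) else NA_integer_)
}

#' Write variant calls as a single-sample VCF
#'
#' Minimal VCF 4.2 with `COUNT`, `COV` and `FREQ` (percent) INFO fields,
#' one record per call.
#'
#' @param calls a `variant_calls` data.frame.
#' @param path output path.
#' @param reference reference string (for the contig header line).
#' @param ref_name contig name.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(calls, path, reference, ref_name = "amplicon") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ref_name, nchar(reference)),
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type\">",
    "##INFO=<ID=COUNT,Number=1,Type=Integer,Description=\"Supporting read count\">",
    "##INFO=<ID=COV,Number=1,Type=Integer,Description=\"Screened coverage\">",
    "##INFO=<ID=FREQ,Number=1,Type=Float,Description=\"Frequency in percent\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tTYPE=%s;COUNT=%d;COV=%d;FREQ=%s",
                  ref_name, calls$pos, calls$ref, calls$alt, calls$filter,
                  calls$type, calls$count, calls$coverage,
                  format(round(calls$frequency, 4), trim = TRUE))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write variant calls as an annotated TSV table
#'
#' @param calls a `variant_calls` data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- calls[, c("pos", "type", "ref", "alt", "count", "coverage",
                   "frequency", "filter")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
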