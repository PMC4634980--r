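#' Mapping parameters
#'
#' Cost model and acceptance filters for read placement. Defaults are the
#' amplicon remapping setting this package models: mismatch cost 2,
#' insertion/deletion cost 3 per base, length fraction 0.5, similarity
#' fraction 0.8, non-specific matches placed randomly. End-trimming
#' thresholds are applied by [trim_reads()] before mapping.
#'
#' @param mismatch_cost,insertion_cost,deletion_cost positive alignment
#'   costs (match costs 0).
#' @param length_fraction minimum fraction of the read inside the alignment.
#' @param similarity_fraction minimum identity within the aligned region.
#' @param trim_quality,trim_min_length Phred end-trim threshold and minimum
#'   surviving read length for [trim_reads()].
#' @param seed integer seed for random placement of non-specific matches;
#'   NULL uses the current RNG state.
#' @return object of class `mapping_params`.
#' @export
mapping_params <- function(mismatch_cost = 2, insertion_cost = 3,
                           deletion_cost = 3, length_fraction = 0.5,
                           similarity_fraction = 0.8, trim_quality = 20L,
                           trim_min_length = 50L, seed = 1L) {
  .assert(all(c(mismatch_cost, insertion_cost, deletion_cost) > 0),
          "alignment costs must be positive")
  .assert(length_fraction > 0 && length_fraction <= 1 &&
            similarity_fraction > 0 && similarity_fraction <= 1,
          "fractions must be in (0, 1]")
  structure(list(mismatch_cost = mismatch_cost,
                 insertion_cost = insertion_cost,
                 deletion_cost = deletion_cost,
                 length_fraction = length_fraction,
                 similarity_fraction = similarity_fraction,
                 trim_quality = as.integer(trim_quality),
                 trim_min_length = as.integer(trim_min_length),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "mapping_params")
}

.qual_ints <- function(qual) utf8ToInt(qual) - 33L

#' Quality end-trim a read set
#'
#' Strips bases below the quality threshold from both read ends (inwards
#' until the first base at or above the threshold) and drops reads shorter
#' than the minimum surviving length.
#'
#' @param reads a `read_set` data.frame (columns `seq`, `qual`).
#' @param trim_quality Phred threshold.
#' @param min_length minimum surviving read length.
#' @return the trimmed `read_set`.
#' @export
trim_reads <- function(reads, trim_quality = 20L, min_length = 50L) {
  n <- nrow(reads)
  keep <- logical(n)
  for (i in seq_len(n)) {
    q <- .qual_ints(reads$qual[i])
    ok <- which(q >= trim_quality)
    if (length(ok) == 0L) next
    a <- ok[1]; b <- ok[length(ok)]
    if (b - a + 1L < min_length) next
    reads$seq[i] <- substr(reads$seq[i], a, b)
    reads$qual[i] <- substr(reads$qual[i], a, b)
    keep[i] <- TRUE
  }
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## core single-orientation, single-read alignment (no RNG seeding here)
.align_one <- function(seq, qual, reference, params, read_id) {
  fwd <- cpp_align_semiglobal(seq, reference, params$mismatch_cost,
                              params$insertion_cost, params$deletion_cost)
  rseq <- .revcomp(seq)
  rev <- cpp_align_semiglobal(rseq, reference, params$mismatch_cost,
                              params$insertion_cost, params$deletion_cost)
  use_rev <- if (rev$cost < fwd$cost) TRUE
    else if (fwd$cost < rev$cost) FALSE
    else runif(1) < 0.5
  a <- if (use_rev) rev else fwd
  oseq <- if (use_rev) rseq else seq
  oqual <- if (use_rev) intToUtf8(rev(utf8ToInt(qual))) else qual
  read_len <- nchar(seq)
  denom <- a$n_match + a$n_mismatch + a$n_ins + a$n_del
  identity <- if (denom > 0) a$n_match / denom else 0
  aligned_fraction <- (read_len - a$n_clip) / read_len
  data.frame(
    read_id = read_id,
    mapped = aligned_fraction >= params$length_fraction &&
      identity >= params$similarity_fraction,
    strand = if (use_rev) "-" else "+",
    ref_start = a$ref_start, cigar = a$cigar, cost = a$cost,
    n_match = a$n_match, n_mismatch = a$n_mismatch,
    n_ins = a$n_ins, n_del = a$n_del, clip = a$n_clip,
    aligned_fraction = aligned_fraction, identity = identity,
    read_len = read_len, seq = oseq, qual = oqual,
    stringsAsFactors = FALSE)
}

#' Align one read to the reference
#'
#' Semi-global minimum-cost placement (match 0, mismatch/gap costs from
#' `params`) with free reference overhangs; both orientations are tried and
#' the cheaper wins. The read is accepted (`mapped = TRUE`) iff the aligned
#' read fraction reaches `length_fraction` and the identity within the
#' aligned region reaches `similarity_fraction`. Equal-cost placements are
#' resolved uniformly at random (reproducible under `params$seed`).
#'
#' @param seq read nucleotide string.
#' @param reference reference nucleotide string.
#' @param params a [mapping_params()].
#' @param qual Phred+33 quality string (defaults to uniform Q40).
#' @param read_id identifier carried into the record.
#' @return one-row alignment record data.frame.
#' @export
align_read <- function(seq, reference, params = mapping_params(),
                       qual = NULL, read_id = "read") {
  .assert(nchar(seq) >= 1L && nchar(reference) >= 1L,
          "read and reference must be non-empty", "sporevar_input_error")
  if (is.null(qual)) qual <- intToUtf8(rep(40L + 33L, nchar(seq)))
  if (is.null(params$seed)) .align_one(seq, qual, reference, params, read_id)
  else .with_seed(params$seed,
                  .align_one(seq, qual, reference, params, read_id))
}

#' Map a read set to the reference
#'
#' Aligns every read with [align_read()] semantics and computes mapping
#' statistics over the accepted reads. Percentages and mean lengths are
#' rounded to the nearest integer, halves away from zero.
#'
#' @param reads a `read_set` data.frame (`id`, `seq`, `qual`).
#' @param reference reference nucleotide string.
#' @param params a [mapping_params()].
#' @param ref_name reference name used in SAM output.
#' @param sam_path optional path; when given the alignment set is written
#'   as SAM.
#' @return object of class `map_result`: `alignments` (one record per
#'   read), `stats` (`n_reads`, `n_mapped`, `percent_mapped`,
#'   `mean_mapped_read_length`), `reference`, `ref_name`.
#' @export
map_all <- function(reads, reference, params = mapping_params(),
                    ref_name = "amplicon", sam_path = NULL) {
  .assert(nrow(reads) >= 1L, "reads must be non-empty",
          "sporevar_input_error")
  run <- function() {
    recs <- vector("list", nrow(reads))
    for (i in seq_len(nrow(reads))) {
      recs[[i]] <- .align_one(reads$seq[i], reads$qual[i], reference,
                              params, reads$id[i])
    }
    do.call(rbind, recs)
  }
  aln <- if (is.null(params$seed)) run() else .with_seed(params$seed, run())
  n_mapped <- sum(aln$mapped)
  stats <- list(
    n_reads = nrow(aln), n_mapped = n_mapped,
    percent_mapped = as.integer(round_half_away(100 * n_mapped / nrow(aln))),
    mean_mapped_read_length = if (n_mapped > 0)
      as.integer(round_half_away(mean(aln$read_len[aln$mapped]))) else
        NA_integer_)
  res <- structure(list(alignments = aln, stats = stats,
                        reference = reference, ref_name = ref_name),
                   class = "map_result")
  if (!is.null(sam_path)) write_sam(res, sam_path)
  res
}

#' @export
print.map_result <- function(x, ...) {
  cat(sprintf("map_result: %d reads, %d mapped (%d%%), mean mapped length %s\n",
              x$stats$n_reads, x$stats$n_mapped, x$stats$percent_mapped,
              x$stats$mean_mapped_read_length))
  invisible(x)
}

#' Write alignments as SAM
#'
#' Emits a valid SAM text file (header `@HD`/`@SQ`/`@PG`; CIGAR with
#' M/I/D/S ops; MAPQ 60 for accepted reads; `NM` edit-distance tag).
#' Rejected reads are written as unmapped records.
#'
#' @param result a [map_all()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sam <- function(result, path) {
  stopifnot(inherits(result, "map_result"))
  a <- result$alignments
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", result$ref_name,
                   nchar(result$reference)),
           "@PG\tID:sporevar\tPN:sporevar")
  flag <- ifelse(a$mapped, ifelse(a$strand == "-", 16L, 0L), 4L)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                  a$read_id, flag,
                  ifelse(a$mapped, result$ref_name, "*"),
                  ifelse(a$mapped, a$ref_start, 0L),
                  ifelse(a$mapped, 60L, 0L),
                  ifelse(a$mapped, a$cigar, "*"),
                  a$seq, a$qual,
                  a$n_mismatch + a$n_ins + a$n_del)
  writeLines(c(hdr, body), path)
  invisible(path)
}

## parse one CIGAR string into op/length vectors
.parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  .assert(length(lens) == length(ops), sprintf("bad CIGAR '%s'", cigar))
  list(op = ops, len = lens)
}

#' Read a SAM file back into an alignment set
#'
#' Reconstructs the alignment records written by [write_sam()], including
#' identity and aligned-fraction fields (derivable from CIGAR + NM).
#'
#' @param path SAM path.
#' @return alignment data.frame in [map_all()] record layout.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  recs <- lapply(body, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    mapped <- !bitwAnd(flag, 4L)
    nm <- as.integer(sub("NM:i:", "", grep("^NM:i:", f, value = TRUE)[1]))
    if (mapped) {
      cg <- .parse_cigar(f[6])
      m_len <- sum(cg$len[cg$op == "M"])
      n_ins <- sum(cg$len[cg$op == "I"])
      n_del <- sum(cg$len[cg$op == "D"])
      clip <- sum(cg$len[cg$op == "S"])
      n_mismatch <- nm - n_ins - n_del
      n_match <- m_len - n_mismatch
      read_len <- nchar(f[10])
      denom <- n_match + n_mismatch + n_ins + n_del
      data.frame(read_id = f[1], mapped = TRUE,
                 strand = if (bitwAnd(flag, 16L)) "-" else "+",
                 ref_start = as.integer(f[4]), cigar = f[6],
                 cost = NA_real_, n_match = n_match, n_mismatch = n_mismatch,
                 n_ins = n_ins, n_del = n_del, clip = clip,
                 aligned_fraction = (read_len - clip) / read_len,
                 identity = if (denom > 0) n_match / denom else 0,
                 read_len = read_len, seq = f[10], qual = f[11],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(read_id = f[1], mapped = FALSE, strand = "+",
                 ref_start = NA_integer_, cigar = NA_character_,
                 cost = NA_real_, n_match = NA_integer_,
                 n_mismatch = NA_integer_, n_ins = NA_integer_,
                 n_del = NA_integer_, clip = NA_integer_,
                 aligned_fraction = NA_real_, identity = NA_real_,
                 read_len = nchar(f[10]), seq = f[10], qual = f[11],
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, recs)
}
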