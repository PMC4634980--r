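#' Unify per-spore variant calls into a variant matrix
#'
#' Rows are exact variant keys (pos, type, ref, alt); identical keys across
#' spores share a row. Cells hold the call frequency in percent, `NA` where
#' a spore has no call for that key.
#'
#' @param call_sets named list of `variant_calls` (one per spore).
#' @param grouping named character vector mapping spore id to isolate id;
#'   defaults to one isolate for all spores.
#' @return object of class `variant_matrix`: `keys` (data.frame pos/type/
#'   ref/alt), `freq` (rows x spores numeric matrix), `samples`,
#'   `isolates` (named vector).
#' @export
unify <- function(call_sets, grouping = NULL) {
  .assert(length(call_sets) >= 1L && !is.null(names(call_sets)),
          "call_sets must be a named list", "sporevar_input_error")
  samples <- names(call_sets)
  if (is.null(grouping)) grouping <- setNames(rep("ISO1", length(samples)),
                                              samples)
  .assert(all(samples %in% names(grouping)),
          "every sample needs an isolate assignment",
          "sporevar_grouping_error")
  keyed <- lapply(call_sets, function(calls) {
    calls <- calls[calls$filter == "PASS", , drop = FALSE]
    k <- paste(calls$pos, calls$type, calls$ref, calls$alt, sep = "|")
    .assert(!anyDuplicated(k), "duplicate variant key within one sample",
            "sporevar_input_error")
    setNames(calls$frequency, k)
  })
  all_keys <- unique(unlist(lapply(keyed, names), use.names = FALSE))
  ## deterministic row order: position, then type rank, then alt
  parts <- strsplit(all_keys, "|", fixed = TRUE)
  keys <- data.frame(
    pos = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    type = vapply(parts, `[`, character(1), 2),
    ref = vapply(parts, `[`, character(1), 3),
    alt = vapply(parts, `[`, character(1), 4),
    stringsAsFactors = FALSE)
  ord <- order(keys$pos, .type_rank[keys$type], keys$alt)
  keys <- keys[ord, , drop = FALSE]
  all_keys <- all_keys[ord]
  rownames(keys) <- NULL
  freq <- matrix(NA_real_, nrow = length(all_keys), ncol = length(samples),
                 dimnames = list(all_keys, samples))
  for (s in samples) freq[names(keyed[[s]]), s] <- keyed[[s]]
  structure(list(keys = keys, freq = freq, samples = samples,
                 isolates = grouping[samples]),
            class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("variant_matrix: %d variants x %d spores (%d isolate(s))\n",
              nrow(x$freq), length(x$samples),
              length(unique(x$isolates))))
  invisible(x)
}

## presence indicator under a frequency threshold (percent); threshold 0
## means "any call counts"
.presence <- function(matrix, threshold_percent) {
  !is.na(matrix$freq) & matrix$freq >= threshold_percent
}

#' Select unique and universal variants under a frequency threshold
#'
#' A variant is "present" in a spore iff it was called there with frequency
#' at or above the threshold (threshold 0: any call counts). Threshold 0
#' recovers variants present in only one spore; threshold 100 recovers
#' variants common to all spores at full frequency.
#'
#' @param matrix a [unify()] result.
#' @param threshold_percent frequency threshold in `[0, 100]`.
#' @return list with `unique_to_one_sample` and `common_to_all`, each the
#'   corresponding subset of `matrix$keys` (with a `sample` column for the
#'   unique set).
#' @export
select_by_threshold <- function(matrix, threshold_percent = 0) {
  stopifnot(inherits(matrix, "variant_matrix"))
  .assert(threshold_percent >= 0 && threshold_percent <= 100,
          "threshold must be in [0, 100]")
  pres <- .presence(matrix, threshold_percent)
  n_present <- rowSums(pres)
  uniq <- which(n_present == 1L)
  common <- which(n_present == ncol(pres))
  u <- matrix$keys[uniq, , drop = FALSE]
  u$sample <- if (length(uniq))
    matrix$samples[apply(pres[uniq, , drop = FALSE], 1L, which)] else
      character(0)
  rownames(u) <- NULL
  cm <- matrix$keys[common, , drop = FALSE]
  rownames(cm) <- NULL
  list(unique_to_one_sample = u, common_to_all = cm)
}

#' Summarise a variant matrix across spores and isolates
#'
#' Counts totals, SNVs, per-gene-region tallies, per-isolate totals and
#' exclusives (variants present only in spores of that isolate), and
#' per-spore exclusives (variants present in exactly one spore).
#' Percentages are integer-rounded, halves away from zero: 47 of 288
#' variants reports as 16%.
#'
#' @param matrix a [unify()] result.
#' @param gene_model optional [gene_model()]; adds per-region tallies
#'   (exon_1, intron_1, ...).
#' @return object of class `comparison_summary`.
#' @export
summarize_comparison <- function(matrix, gene_model = NULL) {
  stopifnot(inherits(matrix, "variant_matrix"))
  pres <- .presence(matrix, 0)
  total <- nrow(pres)
  n_present <- rowSums(pres)
  isolates <- unique(matrix$isolates)

  per_isolate <- lapply(isolates, function(iso) {
    cols <- matrix$samples[matrix$isolates == iso]
    in_iso <- rowSums(pres[, cols, drop = FALSE]) > 0L
    excl <- in_iso & rowSums(pres[, setdiff(matrix$samples, cols),
                                  drop = FALSE]) == 0L
    data.frame(isolate = iso, total = sum(in_iso), exclusive = sum(excl),
               exclusive_pct = as.integer(
                 round_half_away(100 * sum(excl) / total)),
               stringsAsFactors = FALSE)
  })
  per_isolate <- do.call(rbind, per_isolate)

  per_spore <- lapply(matrix$samples, function(sp) {
    iso <- matrix$isolates[[sp]]
    iso_total <- per_isolate$total[per_isolate$isolate == iso]
    excl <- pres[, sp] & n_present == 1L
    data.frame(spore = sp, isolate = iso, n_called = sum(pres[, sp]),
               exclusive = sum(excl),
               exclusive_pct = as.integer(round_half_away(
                 100 * sum(excl) / max(iso_total, 1L))),
               stringsAsFactors = FALSE)
  })
  per_spore <- do.call(rbind, per_spore)

  per_region <- NULL
  if (!is.null(gene_model)) {
    loc <- locate(gene_model, matrix$keys$pos)
    region <- paste0(loc$kind, "_", loc$ordinal)
    per_region <- as.data.frame(table(region), stringsAsFactors = FALSE)
    names(per_region) <- c("region", "n_variants")
  }

  shared <- matrix$keys[n_present == ncol(pres), , drop = FALSE]
  rownames(shared) <- NULL
  structure(list(
    total_variants = total,
    total_snvs = sum(matrix$keys$type == "SNV"),
    per_region = per_region,
    per_isolate = per_isolate,
    per_spore = per_spore,
    shared_by_all = shared,
    n_shared_by_all = nrow(shared)),
    class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf("comparison_summary: %d variants (%d SNVs), %d shared by all spores\n",
              x$total_variants, x$total_snvs, x$n_shared_by_all))
  print(x$per_isolate, row.names = FALSE)
  invisible(x)
}

#' Variant-frequency histogram for one spore
#'
#' Bins called frequencies into `[0,2) [2,20) [20,40) [40,60) [60,80)
#' [80,100]` (percent); the final bin is closed at 100.
#'
#' @param matrix a [unify()] result.
#' @param sample spore id.
#' @return named integer vector of bin counts; sums to the spore's number
#'   of called variants.
#' @export
freq_histogram <- function(matrix, sample) {
  stopifnot(inherits(matrix, "variant_matrix"))
  .assert(sample %in% matrix$samples, sprintf("unknown sample '%s'", sample))
  f <- matrix$freq[, sample]
  f <- f[!is.na(f)]
  edges <- c(0, 2, 20, 40, 60, 80, 100)
  labs <- c("[0,2)", "[2,20)", "[20,40)", "[40,60)", "[60,80)", "[80,100]")
  idx <- findInterval(f, edges, rightmost.closed = TRUE)
  idx[idx == 0L] <- 1L
  counts <- tabulate(idx, nbins = 6L)
  setNames(as.integer(counts), labs)
}

#' Per-position mean SNV frequency track for one isolate
#'
#' For every reference position carrying at least one SNV row, the mean
#' called frequency over the isolate's spores where it was called.
#'
#' @param matrix a [unify()] result.
#' @param isolate isolate id.
#' @return data.frame `pos`, `mean_frequency` (percent), sorted by position.
#' @export
snv_track <- function(matrix, isolate) {
  stopifnot(inherits(matrix, "variant_matrix"))
  cols <- matrix$samples[matrix$isolates == isolate]
  .assert(length(cols) >= 1L, sprintf("unknown isolate '%s'", isolate))
  snv <- matrix$keys$type == "SNV"
  rows <- which(snv & rowSums(!is.na(matrix$freq[, cols, drop = FALSE])) > 0L)
  if (length(rows) == 0L) {
    return(data.frame(pos = integer(0), mean_frequency = numeric(0)))
  }
  mf <- rowMeans(matrix$freq[rows, cols, drop = FALSE], na.rm = TRUE)
  out <- data.frame(pos = matrix$keys$pos[rows], mean_frequency = unname(mf))
  ## positions with several SNV alleles: average over alleles as well
  agg <- aggregate(mean_frequency ~ pos, out, mean)
  agg[order(agg$pos), , drop = FALSE]
}

#' Write a variant matrix (and its grouping) as TSV
#'
#' @param matrix a [unify()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_matrix_tsv <- function(matrix, path) {
  out <- cbind(matrix$keys, as.data.frame(matrix$freq, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a merged multi-sample VCF with per-sample frequencies
#'
#' FORMAT field `FR` carries each spore's call frequency in percent, `.`
#' where absent.
#'
#' @param matrix a [unify()] result.
#' @param path output path.
#' @param reference reference string (contig header).
#' @param ref_name contig name.
#' @return invisibly, `path`.
#' @export
write_merged_vcf <- function(matrix, path, reference,
                             ref_name = "amplicon") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ref_name, nchar(reference)),
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type\">",
    "##FORMAT=<ID=FR,Number=1,Type=Float,Description=\"Frequency percent\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", matrix$samples), collapse = "\t"))
  cells <- apply(matrix$freq, 1L, function(row) {
    paste(ifelse(is.na(row), ".", format(round(row, 4), trim = TRUE)),
          collapse = "\t")
  })
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tTYPE=%s\tFR\t%s",
                  ref_name, matrix$keys$pos, matrix$keys$ref,
                  matrix$keys$alt, matrix$keys$type, cells)
  writeLines(c(hdr, body), path)
  invisible(path)
}
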