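#' Construct an exon/intron gene model
#'
#' A `gene_model` ties a genomic (sense-strand) sequence to an ordered set of
#' exon/intron features, a CDS span, a conserved-domain interval and the
#' length of the predicted N-terminal targeting peptide. All coordinates are
#' 1-based inclusive on the sense strand.
#'
#' Invariants enforced at construction:
#' * features tile `[1, nchar(sequence)]` contiguously, no gaps or overlaps;
#' * exons and introns strictly alternate, starting and ending with an exon;
#' * the CDS (exon bases inside `cds_span`) has length a multiple of 3 and
#'   translates without internal stop codons;
#' * both ends of `domain_interval` fall on exon bases.
#'
#' @param gene_id single character id.
#' @param sequence genomic nucleotide string (A/C/G/T), sense strand.
#' @param features data.frame with columns `kind` ("exon"/"intron"),
#'   `start`, `end` (1-based inclusive), in genomic order.
#' @param cds_span length-2 integer vector `c(start, end)`; the CDS is the
#'   exon bases inside this genomic span, concatenated in exon order.
#' @param domain_interval length-2 integer vector for the conserved
#'   (ferritin-like) domain, or `NULL`. A position is "in domain" iff it is
#'   inside this interval *and* exonic, so a domain starting on exon 1 and
#'   ending on exon 4 is representable with one interval.
#' @param n_terminal_aa_len number of N-terminal residues predicted as
#'   mitochondrial targeting peptide (0 = none annotated).
#' @param metadata free-form named list (e.g. provenance flags for synthetic
#'   stand-in coordinates).
#' @return object of class `gene_model`.
#' @seealso [riaox_gene_model()], [locate()], [extract_cds()]
#' @export
gene_model <- function(gene_id, sequence, features,
                       cds_span = c(1L, nchar(sequence)),
                       domain_interval = NULL,
                       n_terminal_aa_len = 0L,
                       metadata = list()) {
  sequence <- toupper(as.character(sequence))
  .assert(is.character(gene_id) && length(gene_id) == 1L,
          "gene_id must be a single string", "sporevar_model_error")
  .assert(grepl("^[ACGT]+$", sequence),
          "sequence must be a non-empty A/C/G/T string", "sporevar_model_error")
  .assert(is.data.frame(features) &&
            all(c("kind", "start", "end") %in% names(features)),
          "features needs columns kind/start/end", "sporevar_model_error")
  features <- data.frame(kind = as.character(features$kind),
                         start = as.integer(features$start),
                         end = as.integer(features$end),
                         stringsAsFactors = FALSE)
  .assert(all(features$kind %in% c("exon", "intron")),
          "feature kind must be 'exon' or 'intron'", "sporevar_structural_error")
  n <- nchar(sequence)

  ## contiguous tiling of [1, n]
  .assert(features$start[1] == 1L && features$end[nrow(features)] == n &&
            all(features$start <= features$end) &&
            (nrow(features) == 1L ||
               all(features$start[-1] == features$end[-nrow(features)] + 1L)),
          "features must tile [1, sequence length] without gaps or overlaps",
          "sporevar_structural_error")
  ## strict exon/intron alternation, exon-bounded
  expected <- rep(c("exon", "intron"), length.out = nrow(features))
  .assert(all(features$kind == expected) &&
            features$kind[nrow(features)] == "exon",
          "exons and introns must alternate, starting and ending with an exon",
          "sporevar_structural_error")

  cds_span <- as.integer(cds_span)
  .assert(length(cds_span) == 2L && cds_span[1] >= 1L && cds_span[2] <= n &&
            cds_span[1] <= cds_span[2],
          "cds_span out of range", "sporevar_model_error")
  if (!is.null(domain_interval)) {
    domain_interval <- as.integer(domain_interval)
    .assert(length(domain_interval) == 2L &&
              domain_interval[1] >= 1L && domain_interval[2] <= n &&
              domain_interval[1] <= domain_interval[2],
            "domain_interval out of range", "sporevar_model_error")
  }

  ## per-feature ordinal (exon 1, intron 1, exon 2, ...)
  ord <- integer(nrow(features))
  for (k in unique(features$kind)) {
    idx <- features$kind == k
    ord[idx] <- seq_len(sum(idx))
  }
  features$ordinal <- ord

  model <- structure(
    list(gene_id = gene_id, sequence = sequence, features = features,
         cds_span = cds_span, domain_interval = domain_interval,
         n_terminal_aa_len = as.integer(n_terminal_aa_len),
         metadata = metadata),
    class = "gene_model")

  ## CDS invariants
  cds <- extract_cds(model)
  .assert(nchar(cds) %% 3L == 0L,
          sprintf("CDS length %d is not a multiple of 3", nchar(cds)),
          "sporevar_model_error")
  aa <- translate_cds(cds, strip_stop = TRUE)
  # translate_cds errors on internal stops

  if (!is.null(domain_interval)) {
    exonic <- .exonic_positions(model)
    .assert(all(domain_interval %in% exonic),
            "domain_interval ends must fall on exon bases",
            "sporevar_model_error")
  }
  model
}

#' @export
print.gene_model <- function(x, ...) {
  ex <- x$features[x$features$kind == "exon", ]
  cat(sprintf("gene_model '%s': %d bp, %d exon(s) / %d intron(s), CDS %d..%d\n",
              x$gene_id, nchar(x$sequence), nrow(ex),
              sum(x$features$kind == "intron"), x$cds_span[1], x$cds_span[2]))
  invisible(x)
}

## internal: sorted genomic positions of all exon bases
.exonic_positions <- function(model) {
  ex <- model$features[model$features$kind == "exon", ]
  unlist(Map(seq.int, ex$start, ex$end), use.names = FALSE)
}

## internal: genomic positions of CDS bases, in exon order
.cds_positions <- function(model) {
  p <- .exonic_positions(model)
  p[p >= model$cds_span[1] & p <= model$cds_span[2]]
}

#' Extract the coding sequence of a gene model
#'
#' Concatenates CDS bases (exon bases inside the model's `cds_span`) in exon
#' order.
#'
#' @param model a [gene_model()].
#' @return nucleotide string; length is always a multiple of 3 for a valid
#'   model.
#' @export
extract_cds <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  pos <- .cds_positions(model)
  paste(strsplit(model$sequence, "", fixed = TRUE)[[1]][pos], collapse = "")
}

#' Translate a coding sequence
#'
#' Standard-genetic-code translation of a CDS. The terminal stop codon, when
#' present, is not reported; an internal stop raises an error naming the
#' offending codon.
#'
#' @param cds nucleotide string, length a multiple of 3.
#' @param strip_stop drop a terminal stop codon from the output (default).
#' @return amino-acid string (one-letter code).
#' @export
translate_cds <- function(cds, strip_stop = TRUE) {
  cds <- toupper(as.character(cds))
  .assert(nchar(cds) %% 3L == 0L,
          sprintf("CDS length %d is not a multiple of 3", nchar(cds)),
          "sporevar_model_error")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
  internal <- stops[stops > 0 & stops < nchar(aa)]
  .assert(length(internal) == 0L,
          sprintf("internal stop codon at codon %d", internal[1]),
          "sporevar_model_error")
  if (strip_stop && substring(aa, nchar(aa)) == "*") {
    aa <- substring(aa, 1L, nchar(aa) - 1L)
  }
  aa
}

#' Locate genomic positions in a gene model
#'
#' Maps each genomic position to its feature context: feature kind and
#' ordinal (e.g. intron 2), CDS offset, codon index and within-codon phase
#' (all `NA` outside the CDS), and conserved-domain membership.
#'
#' @param model a [gene_model()].
#' @param genomic_pos integer vector of 1-based genomic positions.
#' @return data.frame with one row per position: `pos`, `kind`, `ordinal`,
#'   `cds_offset`, `codon_index`, `phase` (1..3), `in_domain`.
#' @export
locate <- function(model, genomic_pos) {
  stopifnot(inherits(model, "gene_model"))
  genomic_pos <- as.integer(genomic_pos)
  n <- nchar(model$sequence)
  .assert(all(genomic_pos >= 1L & genomic_pos <= n),
          sprintf("position out of range 1..%d", n), "sporevar_bounds_error")
  f <- model$features
  idx <- findInterval(genomic_pos, f$start)
  cdsp <- .cds_positions(model)
  off <- match(genomic_pos, cdsp)
  dom <- if (is.null(model$domain_interval)) rep(FALSE, length(genomic_pos)) else
    genomic_pos >= model$domain_interval[1] &
    genomic_pos <= model$domain_interval[2] &
    f$kind[idx] == "exon"
  data.frame(
    pos = genomic_pos,
    kind = f$kind[idx],
    ordinal = f$ordinal[idx],
    cds_offset = off,
    codon_index = ifelse(is.na(off), NA_integer_, (off - 1L) %/% 3L + 1L),
    phase = ifelse(is.na(off), NA_integer_, (off - 1L) %% 3L + 1L),
    in_domain = dom,
    stringsAsFactors = FALSE)
}

#' Read a gene model from FASTA + annotation files
#'
#' The annotation is a GFF3-like tab-separated file with columns
#' `seqid`, `kind`, `start`, `end` and no header. Kinds `exon` and `intron`
#' define the feature tiling; optional single rows of kind `cds`, `domain`
#' and `n_terminal` carry the CDS span, the conserved-domain interval and the
#' N-terminal peptide length (in the `end` column). Every feature row must
#' reference the FASTA record's id.
#'
#' @param fasta_source path to a FASTA file holding exactly one record.
#' @param annotation_source path to the annotation TSV.
#' @return a validated [gene_model()].
#' @seealso [write_gene_model()] for the bit-exact inverse.
#' @export
load_gene_model <- function(fasta_source, annotation_source) {
  seqs <- Biostrings::readDNAStringSet(fasta_source)
  .assert(length(seqs) == 1L, "FASTA must contain exactly one record",
          "sporevar_model_error")
  gene_id <- sub("\\s.*$", "", names(seqs)[1])
  ann <- read.delim(annotation_source, header = FALSE,
                    col.names = c("seqid", "kind", "start", "end"),
                    stringsAsFactors = FALSE)
  .assert(all(ann$seqid == gene_id),
          "annotation features must reference the FASTA record id",
          "sporevar_model_error")
  feat <- ann[ann$kind %in% c("exon", "intron"), c("kind", "start", "end")]
  cds <- ann[ann$kind == "cds", ]
  dom <- ann[ann$kind == "domain", ]
  nt <- ann[ann$kind == "n_terminal", ]
  gene_model(
    gene_id = gene_id,
    sequence = as.character(seqs[[1]]),
    features = feat,
    cds_span = if (nrow(cds)) c(cds$start[1], cds$end[1]) else
      c(1L, nchar(as.character(seqs[[1]]))),
    domain_interval = if (nrow(dom)) c(dom$start[1], dom$end[1]) else NULL,
    n_terminal_aa_len = if (nrow(nt)) nt$end[1] else 0L)
}

#' Write a gene model to FASTA + annotation files
#'
#' Inverse of [load_gene_model()]; a model round-trips through these files
#' bit-exact.
#'
#' @param model a [gene_model()].
#' @param fasta_path,annotation_path output paths.
#' @return invisibly, the two paths.
#' @export
write_gene_model <- function(model, fasta_path, annotation_path) {
  stopifnot(inherits(model, "gene_model"))
  dna <- Biostrings::DNAStringSet(model$sequence)
  names(dna) <- model$gene_id
  Biostrings::writeXStringSet(dna, fasta_path, width = 70L)
  rows <- data.frame(seqid = model$gene_id,
                     kind = model$features$kind,
                     start = model$features$start,
                     end = model$features$end,
                     stringsAsFactors = FALSE)
  rows <- rbind(rows, data.frame(seqid = model$gene_id, kind = "cds",
                                 start = model$cds_span[1],
                                 end = model$cds_span[2]))
  if (!is.null(model$domain_interval)) {
    rows <- rbind(rows, data.frame(seqid = model$gene_id, kind = "domain",
                                   start = model$domain_interval[1],
                                   end = model$domain_interval[2]))
  }
  if (model$n_terminal_aa_len > 0L) {
    rows <- rbind(rows, data.frame(seqid = model$gene_id, kind = "n_terminal",
                                   start = 1L, end = model$n_terminal_aa_len))
  }
  write.table(rows, annotation_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(fasta_path, annotation_path))
}
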