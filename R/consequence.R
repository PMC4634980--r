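#' Predict the coding consequence of variants
#'
#' Classifies each variant key against the gene model:
#' * fully intronic events -> `intronic`;
#' * exonic SNVs/MNVs -> affected codons are retranslated and classified as
#'   `synonymous`, `missense`, `stop_gained` or `stop_lost` (MNVs spanning
#'   codons report the first altered residue and the most severe class,
#'   stop_gained > stop_lost > missense > synonymous);
#' * exonic Ins/Del/Repl -> `frameshift` when the net length change is not
#'   a multiple of 3, else `inframe_indel`;
#' * events touching both exon and intron bases -> `boundary_spanning`;
#' * exonic bases outside the CDS span (UTR; only possible in models whose
#'   exons extend past the CDS) -> `noncoding`.
#'
#' `in_domain` flags any affected exonic base inside the model's conserved
#' domain interval; `in_n_terminal` flags any affected CDS base within the
#' first `n_terminal_aa_len` codons.
#'
#' @param variants data.frame with columns `pos`, `type`, `ref`, `alt`
#'   (a `variant_calls` object, `matrix$keys`, or the panel truth table).
#' @param model a [gene_model()].
#' @return data.frame: the input keys plus `class`, `aa_change`
#'   (e.g. `"E122D"`, `NA` where not applicable), `in_domain`,
#'   `in_n_terminal`.
#' @export
predict_consequence <- function(variants, model) {
  stopifnot(inherits(model, "gene_model"))
  n <- nrow(variants)
  cds <- extract_cds(model)
  cds_pos <- .cds_positions(model)
  out_class <- character(n)
  out_aa <- rep(NA_character_, n)
  out_dom <- logical(n)
  out_nt <- logical(n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    r <- .predict_one(v$pos, v$type, v$ref, v$alt, model, cds, cds_pos)
    out_class[i] <- r$class
    out_aa[i] <- r$aa_change
    out_dom[i] <- r$in_domain
    out_nt[i] <- r$in_n_terminal
  }
  out <- data.frame(pos = variants$pos, type = variants$type,
                    ref = variants$ref, alt = variants$alt,
                    class = out_class, aa_change = out_aa,
                    in_domain = out_dom, in_n_terminal = out_nt,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.predict_one <- function(pos, type, ref, alt, model, cds, cds_pos) {
  seq_len_model <- nchar(model$sequence)
  .assert(pos >= 1L && pos + nchar(ref) - 1L <= seq_len_model,
          "variant coordinates outside the model", "sporevar_input_error")
  .assert(substr(model$sequence, pos, pos + nchar(ref) - 1L) == ref,
          sprintf("ref allele '%s' does not match the reference at %d",
                  ref, pos),
          "sporevar_input_error")
  ## genomic positions affected by the event
  affected <- switch(type,
    SNV = pos,
    MNV = pos:(pos + nchar(ref) - 1L),
    Ins = pos,                                   # anchor base
    Del = (pos + 1L):(pos + nchar(ref) - 1L),    # deleted bases
    Repl = pos:(pos + nchar(ref) - 1L))
  loc <- locate(model, affected)
  kinds <- unique(loc$kind)
  in_domain <- any(loc$in_domain)
  nt_span <- 3L * model$n_terminal_aa_len
  in_nt <- any(!is.na(loc$cds_offset) & loc$cds_offset <= nt_span)
  if (length(kinds) > 1L) {
    return(list(class = "boundary_spanning", aa_change = NA_character_,
                in_domain = in_domain, in_n_terminal = in_nt))
  }
  if (kinds == "intron") {
    return(list(class = "intronic", aa_change = NA_character_,
                in_domain = in_domain, in_n_terminal = in_nt))
  }
  ## exonic
  if (type %in% c("Ins", "Del", "Repl")) {
    net <- nchar(alt) - nchar(ref)
    cls <- if (net %% 3L != 0L) "frameshift" else "inframe_indel"
    return(list(class = cls, aa_change = NA_character_,
                in_domain = in_domain, in_n_terminal = in_nt))
  }
  ## SNV / MNV: retranslate affected codons
  offs <- loc$cds_offset
  if (anyNA(offs)) {
    ## exonic but outside the CDS (UTR bases): no aa consequence possible
    return(list(class = "noncoding", aa_change = NA_character_,
                in_domain = in_domain, in_n_terminal = in_nt))
  }
  codons <- unique((offs - 1L) %/% 3L + 1L)
  cds_chars <- strsplit(cds, "", fixed = TRUE)[[1]]
  mut <- cds_chars
  alt_chars <- strsplit(alt, "", fixed = TRUE)[[1]]
  mut[offs] <- alt_chars
  changes <- list()
  for (ci in codons) {
    idx <- (3L * (ci - 1L) + 1L):(3L * ci)
    ref_aa <- .codon_aa(paste(cds_chars[idx], collapse = ""))
    alt_aa <- .codon_aa(paste(mut[idx], collapse = ""))
    changes[[length(changes) + 1L]] <-
      list(ci = ci, ref_aa = ref_aa, alt_aa = alt_aa,
           changed = ref_aa != alt_aa)
  }
  sev <- vapply(changes, function(ch) {
    if (!ch$changed) return(1L)
    if (ch$alt_aa == "*") return(4L)
    if (ch$ref_aa == "*") return(3L)
    2L
  }, integer(1))
  cls <- c("synonymous", "missense", "stop_lost", "stop_gained")[max(sev)]
  first <- changes[[if (any(sev > 1L)) which(sev > 1L)[1] else 1L]]
  aa_change <- sprintf("%s%d%s", first$ref_aa, first$ci, first$alt_aa)
  list(class = cls, aa_change = aa_change,
       in_domain = in_domain, in_n_terminal = in_nt)
}

.codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Write consequence predictions as TSV
#'
#' @param consequences a [predict_consequence()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_consequence_tsv <- function(consequences, path) {
  write.table(consequences, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
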