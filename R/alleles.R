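## Shared allele conventions.
##
## Variant keys are (pos, type, ref, alt) with VCF-style anchoring:
##   SNV  ref "A"  alt "T"          (1 -> 1)
##   MNV  ref "AC" alt "TG"         (k -> k, k >= 2)
##   Ins  ref "A"  alt "AT"         (anchor base + inserted bases)
##   Del  ref "AT" alt "A"          (anchor base + deleted bases -> anchor)
##   Repl ref "AC" alt "G"          (j -> k, j != k, both >= 1, unanchored)
## Indels are left-aligned against the reference. The same helpers are used
## by the truth generator and the caller so keys compare exactly.

#' Classify a ref/alt allele pair
#'
#' @param ref,alt allele strings under the package's anchoring convention.
#' @return one of "SNV", "MNV", "Ins", "Del", "Repl".
#' @export
classify_alleles <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 0L || na == 0L) stop("alleles must be non-empty (anchored form)")
  if (nr == na) {
    if (nr == 1L) return("SNV")
    return("MNV")
  }
  if (nr == 1L && na > 1L && substring(alt, 1L, 1L) == ref) return("Ins")
  if (na == 1L && nr > 1L && substring(ref, 1L, 1L) == alt) return("Del")
  "Repl"
}

## left-align an anchored insertion (anchor pos, inserted string s)
.left_align_ins <- function(pos, inserted, reference) {
  L <- nchar(inserted)
  while (pos > 1L &&
         substr(reference, pos, pos) == substr(inserted, L, L)) {
    inserted <- paste0(substr(inserted, L, L), substr(inserted, 1L, L - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, inserted = inserted)
}

## left-align an anchored deletion (anchor pos, L deleted bases at pos+1..pos+L)
.left_align_del <- function(pos, del_len, reference) {
  while (pos > 1L &&
         substr(reference, pos, pos) ==
           substr(reference, pos + del_len, pos + del_len)) {
    pos <- pos - 1L
  }
  pos
}

## build the anchored key for an indel event after left-alignment
.ins_key <- function(pos, inserted, reference) {
  la <- .left_align_ins(pos, inserted, reference)
  anchor <- substr(reference, la$pos, la$pos)
  list(pos = la$pos, ref = anchor, alt = paste0(anchor, la$inserted))
}

.del_key <- function(pos, del_len, reference) {
  p <- .left_align_del(pos, del_len, reference)
  anchor <- substr(reference, p, p)
  list(pos = p, ref = substr(reference, p, p + del_len), alt = anchor)
}

## apply a set of variant events to a reference string; events carry
## pos/ref/alt in the uniform "replace reference[pos .. pos+nchar(ref)-1]
## by alt" form that the anchoring convention guarantees
.apply_events <- function(reference, events) {
  if (nrow(events) == 0L) return(reference)
  events <- events[order(-events$pos), , drop = FALSE]
  out <- reference
  for (k in seq_len(nrow(events))) {
    p <- events$pos[k]
    w <- nchar(events$ref[k])
    out <- paste0(substr(out, 1L, p - 1L), events$alt[k],
                  substring(out, p + w))
  }
  out
}

## run expr with a private RNG state seeded at `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
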