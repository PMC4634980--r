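#' Round half away from zero
#'
#' Integer rounding used for every percentage and mean this package reports.
#' Base R's `round()` rounds half to even; the summary conventions here
#' (e.g. 47/288 -> 16%) require the commercial rule instead.
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, ties away from zero.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 16.32))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

## internal: deterministic small hash of a string, for per-stage seed fan-out
.stage_seed <- function(global_seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((as.numeric(global_seed) * 7919 + h) %% 2147483629L)
}

.assert <- function(cond, msg, class = "sporevar_error") {
  if (!isTRUE(cond)) {
    stop(errorCondition(msg, class = c(class, "error", "condition")))
  }
  invisible(TRUE)
}

## internal: maximal homopolymer runs of a sequence string
## returns data.frame(start, end, base, length) in 1-based coordinates
.homopolymer_runs <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts, end = ends, base = r$values,
             length = r$lengths, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
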