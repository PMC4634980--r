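## Independent oracles and fixture builders used across the suite.

## -- standard genetic code, written out independently of the implementation
oracle_codon_table <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(b, b, paste0), b,
                            function(x, y) paste0(x, y)))
  codons <- character(64)
  k <- 0L
  for (x in b) for (y in b) for (z in b) {
    k <- k + 1L
    codons[k] <- paste0(x, y, z)
  }
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aas, codons)
})

oracle_translate <- function(cds) {
  n <- nchar(cds) / 3
  paste(vapply(seq_len(n), function(i) {
    oracle_codon_table[[substr(cds, 3 * i - 2, 3 * i)]]
  }, character(1)), collapse = "")
}

## -- brute-force semi-global alignment cost by memoized recursion,
##    independent of the DP layout in the implementation
oracle_align_cost <- function(read, ref, mismatch = 2, gap = 3) {
  m <- nchar(read); n <- nchar(ref)
  rd <- strsplit(read, "")[[1]]; rf <- strsplit(ref, "")[[1]]
  memo <- new.env(hash = TRUE)
  ## cost of aligning read[i..m] given next reference position j (1..n+1),
  ## reference suffix free once the read is exhausted
  rec <- function(i, j) {
    if (i > m) return(0)
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- Inf
    if (j <= n) {
      best <- min(best, rec(i + 1, j + 1) +
                    if (rd[i] == rf[j]) 0 else mismatch)
      best <- min(best, rec(i, j + 1) + gap)    # delete reference base
    }
    best <- min(best, rec(i + 1, j) + gap)      # insert read base
    memo[[key]] <- best
    best
  }
  ## free reference prefix: best over all start positions
  min(vapply(1:(n + 1), function(j) rec(1, j), numeric(1)))
}

## -- deterministic toy gene model with a clean ORF
## exon/intron lengths in nt; exon lengths must sum to a multiple of 3
toy_gene_model <- function(exon_len = c(18L, 12L), intron_len = c(8L),
                           seed = 42L, domain_interval = NULL,
                           n_terminal_aa_len = 0L) {
  codon_of <- c(M = "ATG", A = "GCT", S = "TCT", T = "ACT", L = "CTT",
                K = "AAA", V = "GTT", I = "ATT", R = "CGT", D = "GAT",
                G = "GGT", F = "TTT", P = "CCT", N = "AAT", Q = "CAA",
                E = "GAA", W = "TGG", Y = "TAT", H = "CAT", C = "TGT")
  n_cds <- sum(exon_len)
  stopifnot(n_cds %% 3L == 0L, n_cds >= 6L)
  n_aa <- n_cds / 3L - 1L
  set.seed(seed)
  aa <- c("M", sample(names(codon_of)[-1], n_aa - 1L, replace = TRUE))
  cds <- paste0(paste(codon_of[aa], collapse = ""), "TAA")
  introns <- vapply(intron_len, function(l) {
    paste0("GT", paste(sample(c("A", "C", "T"), l - 4L, replace = TRUE),
                       collapse = ""), "AG")
  }, character(1))
  ee <- cumsum(exon_len); es <- ee - exon_len + 1L
  exons <- substring(cds, es, ee)
  pieces <- character(0)
  kinds <- character(0)
  for (i in seq_along(exon_len)) {
    pieces <- c(pieces, exons[i]); kinds <- c(kinds, "exon")
    if (i <= length(intron_len)) {
      pieces <- c(pieces, introns[i]); kinds <- c(kinds, "intron")
    }
  }
  lens <- nchar(pieces)
  ends <- cumsum(lens); starts <- ends - lens + 1L
  gene_model("toy", paste(pieces, collapse = ""),
             data.frame(kind = kinds, start = starts, end = ends),
             domain_interval = domain_interval,
             n_terminal_aa_len = n_terminal_aa_len)
}

## -- fabricate a mapped alignment record directly (for caller unit tests)
fake_alignment <- function(seq, ref_start = 1L, cigar = NULL, qual = NULL,
                           read_id = "r1") {
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  if (is.null(qual)) qual <- strrep(rawToChar(as.raw(40 + 33)), nchar(seq))
  data.frame(read_id = read_id, mapped = TRUE, strand = "+",
             ref_start = ref_start, cigar = cigar, cost = 0,
             n_match = nchar(seq), n_mismatch = 0L, n_ins = 0L, n_del = 0L,
             clip = 0L, aligned_fraction = 1, identity = 1,
             read_len = nchar(seq), seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

## variant key string for set comparisons
vkey <- function(d) paste(d$pos, d$type, d$ref, d$alt)
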