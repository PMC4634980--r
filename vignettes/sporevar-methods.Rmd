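---
title: "Within-spore allele diversity from deep amplicon sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-spore allele diversity from deep amplicon sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporevar)
```

## The problem

Arbuscular mycorrhizal fungi (AMF) such as *Rhizophagus irregularis* are
heterokaryotic: a single mature spore carries hundreds of nuclei that are not
genetically identical. Deep amplicon sequencing of one gene from one spore
therefore does not produce a clean diploid genotype but a spectrum of allele
frequencies, from fractions of a percent up to fixation. `sporevar`
implements the full desk-side analysis for such a design, modelled on a
single-gene amplicon of the alternative oxidase gene (*RiAOX*, a ~1.2 kb
amplicon over a 4-exon/3-intron gene): read mapping with explicit costs and
acceptance filters, quality-score low-frequency variant calling with
homopolymer (pyro-error) removal, cross-spore/cross-isolate comparison under
frequency thresholds, and amino-acid consequence prediction — plus a
truth-annotated read simulator so that every stage is testable without
external data.

## Gene model

A `gene_model` ties the genomic sense-strand sequence to an ordered
exon/intron tiling, a CDS span, a conserved-domain interval and an
N-terminal peptide length. Coordinates are 1-based inclusive everywhere.
`riaox_gene_model()` builds a synthetic stand-in with the published
architecture: exons of 444, 116, 188 and 284 nt and introns of 69, 81 and
68 nt. The published exon lengths (with exon 4 printed as 281 nt) sum to
1029 nt, while the coding sequence is given as 1032 nt and the gene as
1250 nt; extending exon 4 by 3 nt reconciles both totals simultaneously
(444+116+188+284 = 1032 and 1032+69+81+68 = 1250), so the fixture adopts
exon 4 = 284 nt and flags the adjustment in its metadata. The nucleotide
sequence itself is a deterministic synthetic construction (a clean ORF with
no internal stops), not the deposited sequence; analyses that depend on the
real bases cannot be reproduced from it, only structural arithmetic and
classification behaviour.

The conserved ferritin-like domain starts on exon 1 and extends into exon 4;
it is stored as one genomic interval, and a position counts as "in domain"
only when it is both inside the interval and exonic. Four glutamates and two
histidines — stand-ins for the universally conserved di-iron-center ligands
— are planted at known codons inside exon 3, so consequence tests can verify
that a missense at those positions reports the correct reference residue.
The predicted N-terminal targeting region is stored as 52 residues; the
source literature prints "52 bp", but targeting-peptide predictors report
peptide lengths, so the value is interpreted as amino acids.

## Synthetic data: what it emulates, and what it does not

`make_panel()` allocates variants over three scopes — shared by all spores,
unique to one isolate, unique to one spore — and realises them as a finite
nuclear mixture (default 100 nuclei per spore). Realising frequencies as a
mixture rather than per-read coin flips matters: variants on the same
nucleus co-occur on reads, which is exactly what MNV merging must detect.
Frequencies are snapped to the `1/n_nuclei` grid with a minimum of one
nucleus, so recorded truth frequencies are exact. The default frequency
sampler draws 75% of variants from a low band (0.5–20%) and the rest from a
near-fixed band (80–100%), echoing the observed shape of within-spore
frequency spectra in this system (most variants rare, a minority near
fixation).

Placement rules make the truth set *representation-stable*: positions are
drawn without replacement at least 6 nt apart (so distinct truth variants
are never merged into one call), at least 25 nt from the reference ends
(where uniformly placed read windows leave thin coverage), and indels are
only placed in contexts where their left-aligned representation is unique —
outside homopolymer runs of length ≥ 3 and with inserted/deleted bases
distinct from their immediate context. Replacements additionally require a
locally unambiguous decomposition (pairwise-distinct context, deleted base
not in a run ≥ 3). Contexts that cannot host a clean indel fall back to an
SNV. These rules are generator choices, not caller assumptions: they ensure
that on error-free data the caller's output is comparable to the truth by
exact key, which is what the recovery tests assert. Real data contain
ambiguous events that no exact-key comparison can resolve; the tests
deliberately do not claim otherwise.

`simulate_reads()` draws each read from the spore's haplotype mixture, from
a uniform window, on either strand. Per-base Phred qualities come from a
clamped normal (default mean 28, sd 6, range 2–40) and substitution errors
are injected with probability `10^(-Q/10)`, so the emitted quality string is
consistent with the error process — this is what makes the caller's
quality-screening meaningful on simulated data. Homopolymer indel errors
emulate pyro-type chemistry (the platform family this design targets):
within each source-sequence run of length `r >= 3` an indel is injected with
probability `rate * (r - 1)`, default rate 0.001 per run. No public error
profile exists for the original run, so this model is an assumption recorded
here, not a literature value. Whole-genome-amplification chimeras, PCR
duplicates and paired-end structure are out of scope.

Default read geometry is mean 143 nt (the published mean mapped read length)
with sd 25. Per-spore read counts in the original study range from ~4.5k to
~113k; the package defaults to 2,000 reads per spore, which gives ~200-fold
coverage of a 1.2 kb amplicon — deep enough to resolve the 1% detection
floor — while keeping a full 9-spore run on a laptop in minutes. All
problem sizes in the test-suite (700 reads per spore for recovery, ~1,100×
coverage for frequency calibration) were chosen on the same reasoning.

## Mapping

`align_read()` performs semi-global alignment under explicit costs — match
0, mismatch 2, insertion/deletion 3 per base — with free reference
overhangs, so a read may sit anywhere on the amplicon. Both orientations
are tried; the cheaper wins. Read bases that fall beyond a reference end
are rendered as soft clips in the CIGAR (they keep their gap cost in the
optimisation, which keeps the cost model total and oracle-checkable).
Acceptance requires an aligned read fraction ≥ 0.5 and an identity within
the aligned region ≥ 0.8, with identity defined as
matches / (matches + mismatches + alignment-internal gap bases).

Two tie-break rules are worth stating precisely. Equal-cost *placements*
(e.g. a read matching two identical reference segments) are first screened
by a deterministic secondary criterion — fewest mismatches along the
traceback — and any remaining ties are resolved uniformly at random under
the mapping seed, the non-specific-match policy. Genuine repeat placements
have identical op composition, so the mismatch screen never biases them;
what it removes are *representation* ties, where a read ending a few bases
past an indel can be written either as a gap or as an equal-cost mismatch
tail. Equal-cost *paths* within one placement are resolved by a fixed
precedence: match, then deletion, then insertion, then mismatch. Both rules
push every read carrying the same event toward the same representation (a
2 nt deletion always appears as a deletion, never as an equal-cost scatter
of mismatches), which the caller's exact-key aggregation depends on.

Reads are end-trimmed before mapping (default: strip bases below Phred 20
from both ends, discard reads shorter than 50 nt). The source procedure
states that trimming occurred but not its thresholds; these defaults are
package choices and are configurable.

## Variant calling

`call_variants()` proceeds in five steps.

1. **Quality screening.** A read base enters the pileup iff its own quality
   is ≥ 20 and the mean quality of read bases within ±5 positions (window
   truncated at read ends, central base included) is ≥ 15. Screened-out
   bases are excluded from counts *and* coverage, so frequency remains a
   property of trusted observations. Additionally, bases within 5 nt of
   either read end are excluded (`read_end_exclusion`), and indel
   observations within 10 nt of an end (`indel_end_exclusion`): a read
   whose window truncates an indel is systematically re-aligned as end
   mismatches or equal-cost split gaps, and those artifact observations
   live only near read ends — split-gap forms reach somewhat deeper than
   substitution forms, hence the larger indel mask.
2. **Candidates.** Each non-reference allele — substitutions, and anchored,
   left-aligned indels — with screened coverage ≥ 10 and frequency
   (100·count/coverage) ≥ 1% becomes a candidate.
3. **Pyro filter.** An insertion/deletion candidate whose (monomeric) event
   lies in a reference homopolymer run of length ≥ 3 and whose frequency is
   below 80% is removed. The 0.8 cutoff is the modelled procedure's own
   setting; its consequence — only near-fixed homopolymer indels survive —
   is inherited deliberately.
4. **Merging.** Span-adjacent candidates whose supporting reads co-occur
   (fraction of carriers among reads covering the joint span that carry any
   constituent ≥ 0.5) are connected; each connected component merges into
   one call — all-substitution components into an MNV, mixed
   substitution/indel components into a replacement (Repl) — with
   constituent calls suppressed. A merge is cancelled if the joint support
   is empty, events conflict, or the merged record would itself violate the
   thresholds; the component then reports its members separately. The
   co-occurrence threshold and the Repl construction are package choices
   (the modelled caller's internal rule is unpublished), exposed as
   parameters.
5. **Ordering.** Output is sorted by position, then type
   (SNV < MNV < Ins < Del < Repl), then alt allele — fully deterministic.

Coverage for an indel is taken at its left-aligned anchor (floored at the
supporting count in the rare case a shifted anchor has lower screened
coverage). Whether "minimum coverage" should count raw or screened depth is
unspecified in the modelled procedure; screened depth was chosen so that
count ≤ coverage always holds.

## Comparison and consequence

`unify()` joins per-spore calls by exact key (pos, type, ref, alt); near
misses (same position, different allele) are distinct rows by design —
fuzzy matching is out of scope. `select_by_threshold()` implements the
two published selections with one parameter: presence means "called with
frequency ≥ threshold", so threshold 0 recovers variants present in only
one spore and threshold 100 recovers variants common to all spores at full
frequency. `summarize_comparison()` reports totals, per-region tallies,
per-isolate exclusives and per-spore exclusives; all percentages round to
the nearest integer, halves away from zero — the rule that reproduces the
published 47/288 → 16%, 80/288 → 28% and 54/288 → 19%. Histogram bins are
`[0,2) [2,20) [20,40) [40,60) [60,80) [80,100]`: the outer bins are named
in the source material, the interior 20%-wide bins are a package choice.

`predict_consequence()` classifies variants against the gene model:
intronic; synonymous/missense/stop for exonic SNVs and MNVs by codon
retranslation (MNVs spanning codons report the first altered residue and
the most severe class); frameshift vs in-frame for exonic indels by the
net-length mod-3 rule; `boundary_spanning` as a terminal class for events
touching both exon and intron bases (no splice-site modelling is
attempted).

## Reproducibility

`run_pipeline()` drives one seeded end-to-end run. A single global seed
fans out to per-stage seeds through a fixed stage-name derivation, so any
stage can be re-run in isolation and reproduce; the manifest records every
effective parameter and the MD5 of every artifact, and reruns with the same
configuration are byte-identical. The interface of the package is its R
functions and this vignette; each pipeline stage (simulate, map, call,
compare, annotate) is an exported function, and `run_pipeline()` composes
them.

## Known limitations

* The published per-spore variant counts (288 variants, 93 SNVs, 13 shared)
  derive from reads without a usable public accession and from a
  closed-source caller; they are not reproducible from this package and are
  used only as bookkeeping inputs (totals, means, percentages).
* The read simulator does not model amplification chimeras, strand bias, or
  position-dependent error rates; passing recovery tests show the pipeline
  is internally consistent, not that it matches any particular instrument.
* Exact-key recovery is only guaranteed for representation-stable truth
  sets (see the placement rules above); ambiguous indels in low-complexity
  contexts are a fundamental limit of exact-key comparison, not of the
  caller alone.
* The aligner is a full dynamic program per read — appropriate for a 1.2 kb
  amplicon at desk scale, not a seed-and-extend mapper for genome-scale
  input.
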