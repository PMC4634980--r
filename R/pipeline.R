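#' Per-spore summary table with TOTAL and Mean rows
#'
#' Mirrors the standard per-spore bookkeeping table of a single-spore
#' amplicon study: one row per spore with read counts, percent mapped,
#' average mapped read length and average variant/SNV coverage, followed by
#' a TOTAL row (read counts only) and a Mean row (per-column means rounded
#' to the nearest integer, half away from zero).
#'
#' @param per_spore data.frame with columns `sample`, `n_reads`,
#'   `percent_mapped`, `mean_mapped_read_length`,
#'   `average_variant_coverage`, `average_snv_coverage` (extra columns are
#'   dropped; `NA`s are excluded from means).
#' @return data.frame with the spore rows plus `TOTAL` and `Mean` rows.
#' @export
summary_table <- function(per_spore) {
  cols <- c("n_reads", "percent_mapped", "mean_mapped_read_length",
            "average_variant_coverage", "average_snv_coverage")
  .assert(nrow(per_spore) >= 1L && all(c("sample", cols) %in%
                                         names(per_spore)),
          "per_spore must have sample plus the five statistic columns",
          "sporevar_input_error")
  tab <- per_spore[, c("sample", cols)]
  total <- data.frame(sample = "TOTAL", n_reads = sum(tab$n_reads),
                      percent_mapped = NA, mean_mapped_read_length = NA,
                      average_variant_coverage = NA,
                      average_snv_coverage = NA)
  means <- vapply(cols, function(cl) {
    v <- tab[[cl]]
    if (all(is.na(v))) NA_real_ else round_half_away(mean(v, na.rm = TRUE))
  }, numeric(1))
  mean_row <- data.frame(sample = "Mean", t(means))
  names(mean_row) <- c("sample", cols)
  out <- rbind(tab, total, mean_row)
  rownames(out) <- NULL
  out
}

#' Run the full simulate-map-call-compare-annotate pipeline
#'
#' Orchestrates one reproducible end-to-end run on a synthetic panel:
#' for every spore, simulate reads, quality-trim, map, and call variants;
#' then unify calls across spores, compute the comparison summary, frequency
#' histograms and per-isolate SNV tracks, predict coding consequences
#' against the gene model, and write every artifact plus a manifest with all
#' effective parameters, the seed and MD5 digests of the outputs. Reruns
#' with the same configuration and seed are byte-identical.
#'
#' A single global `seed` fans out to per-stage seeds through a fixed
#' stage-name derivation, so individual stages can be re-run in isolation
#' and still reproduce.
#'
#' @param out_dir output directory (created if missing).
#' @param seed global integer seed.
#' @param model a [gene_model()]; its sequence is the mapping reference.
#' @param panel optional pre-built [make_panel()]; by default a panel is
#'   built on the model sequence with `panel_args`.
#' @param panel_args list of arguments for [make_panel()] (less
#'   `reference` and `seed`).
#' @param sim_args list of arguments for [read_sim_config()] (less `seed`).
#' @param mapping a [mapping_params()] (its seed is replaced by a derived
#'   stage seed).
#' @param caller a [caller_params()].
#' @param unique_threshold,common_threshold frequency thresholds (percent)
#'   for the unique-to-one-spore and common-to-all selections.
#' @return (invisibly) a list with `panel`, `map_results`, `call_sets`,
#'   `matrix`, `summary`, `selections`, `consequences`, `summary_table`,
#'   `manifest`, `files`.
#' @export
run_pipeline <- function(out_dir, seed = 1L, model = riaox_gene_model(),
                         panel = NULL,
                         panel_args = list(n_isolates = 3L,
                                           n_spores_per_isolate = 3L,
                                           n_shared = 5L,
                                           n_isolate_unique = 4L,
                                           n_spore_unique = 2L),
                         sim_args = list(n_reads = 2000L),
                         mapping = mapping_params(),
                         caller = caller_params(),
                         unique_threshold = 0, common_threshold = 100) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(panel)) {
    panel <- do.call(make_panel, c(
      list(reference = model$sequence, seed = .stage_seed(seed, "panel")),
      panel_args))
  }
  files <- character(0)
  add_file <- function(p) { files <<- c(files, p); p }

  write_gene_model(model, add_file(file.path(out_dir, "reference.fasta")),
                   add_file(file.path(out_dir, "gene_model.tsv")))
  write_truth(panel, add_file(file.path(out_dir, "truth.tsv")),
              add_file(file.path(out_dir, "truth.vcf")))

  spores <- panel$spores$spore_id
  map_results <- list()
  call_sets <- list()
  per_spore <- list()
  for (sp in spores) {
    cfg <- do.call(read_sim_config, c(
      sim_args, list(seed = .stage_seed(seed, paste0("sim_", sp)))))
    reads <- simulate_reads(panel, sp, cfg,
                            fastq_path = add_file(
                              file.path(out_dir, paste0(sp, ".fastq"))))
    reads <- trim_reads(reads, mapping$trim_quality,
                        mapping$trim_min_length)
    mp <- mapping
    mp$seed <- .stage_seed(seed, paste0("map_", sp))
    mr <- map_all(reads, panel$reference, mp, ref_name = model$gene_id,
                  sam_path = add_file(file.path(out_dir,
                                                paste0(sp, ".sam"))))
    calls <- call_variants(mr, params = caller)
    write_vcf(calls, add_file(file.path(out_dir, paste0(sp, ".vcf"))),
              panel$reference, model$gene_id)
    write_calls_tsv(calls,
                    add_file(file.path(out_dir, paste0(sp, "_calls.tsv"))))
    cstats <- caller_stats(calls)
    per_spore[[sp]] <- data.frame(
      sample = sp, n_reads = mr$stats$n_reads,
      percent_mapped = mr$stats$percent_mapped,
      mean_mapped_read_length = mr$stats$mean_mapped_read_length,
      average_variant_coverage = cstats$average_variant_coverage,
      average_snv_coverage = cstats$average_snv_coverage,
      stringsAsFactors = FALSE)
    map_results[[sp]] <- mr
    call_sets[[sp]] <- calls
  }

  grouping <- setNames(panel$spores$isolate, panel$spores$spore_id)
  mat <- unify(call_sets, grouping)
  write_matrix_tsv(mat, add_file(file.path(out_dir, "variant_matrix.tsv")))
  write_merged_vcf(mat, add_file(file.path(out_dir, "merged.vcf")),
                   panel$reference, model$gene_id)
  selections <- list(
    unique = select_by_threshold(mat, unique_threshold),
    common = select_by_threshold(mat, common_threshold))
  summ <- summarize_comparison(mat, model)
  for (iso in unique(panel$spores$isolate)) {
    trk <- snv_track(mat, iso)
    write.table(trk, add_file(file.path(out_dir,
                                        paste0("snv_track_", iso, ".tsv"))),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cons <- predict_consequence(mat$keys, model)
  write_consequence_tsv(cons,
                        add_file(file.path(out_dir, "consequences.tsv")))

  stab <- summary_table(do.call(rbind, per_spore))
  write.table(stab, add_file(file.path(out_dir, "summary_table.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    seed = seed,
    panel_args = panel_args, sim_args = sim_args,
    mapping = unclass(mapping), caller = unclass(caller),
    unique_threshold = unique_threshold,
    common_threshold = common_threshold,
    n_truth_variants = nrow(panel$truth),
    outputs = as.list(setNames(unname(tools::md5sum(files)),
                               basename(files))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(panel = panel, map_results = map_results,
                 call_sets = call_sets, matrix = mat, summary = summ,
                 selections = selections, consequences = cons,
                 summary_table = stab, manifest = manifest,
                 files = c(files, manifest_path)))
}
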