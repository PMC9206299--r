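#' Run the full combination-screen analysis
#'
#' One-command reproduction of the screen analysis path: read (or accept)
#' normalized viability records, assemble every dose matrix, compute Bliss
#' delta matrices and scalar synergy scores, summarize replicates, rank
#' compounds by genotype difference, and write scores, ranking, QC and a
#' machine-readable manifest to an output directory.
#'
#' @param input Path to a long-format screen CSV/TSV, or a plate-record
#'   `data.frame` already in memory.
#' @param out_dir Output directory (created if needed).
#' @param value_kind `"raw"` (normalized here first) or `"normalized"`.
#' @param domain Aggregation domain for [synergy_score()].
#' @param size Grid size required per matrix.
#' @param heatmap Write a percent-inhibition heatmap PNG of the top-ranked
#'   compound's matrix per deficient cell line?
#' @param seed Recorded in the manifest (the analysis itself is
#'   deterministic; the seed documents any upstream generation).
#' @return Invisibly, a list with `scores`, `ranking`, `qc` and
#'   `manifest` (also written as TSV/JSON under `out_dir`).
#' @export
run_full_screen <- function(input, out_dir, value_kind = "normalized",
                            domain = "combinations_only", size = 6,
                            heatmap = TRUE, seed = NA) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- if (is.character(input)) {
    read_screen_table(input, value_kind = value_kind)
  } else {
    input
  }
  if (identical(value_kind, "raw")) {
    records <- normalize_viability(records)
  }
  sres <- score_screen(records, domain = domain, size = size)
  ranking <- genotype_difference_ranking(sres)

  scores_path <- file.path(out_dir, "scores.tsv")
  write.table(sres$summaries, scores_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  ranking_path <- file.path(out_dir, "ranking.tsv")
  write.table(ranking, ranking_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  qc_path <- file.path(out_dir, "qc.tsv")
  write.table(sres$qc, qc_path, sep = "\t", row.names = FALSE, quote = FALSE)

  if (heatmap && nrow(ranking) > 0) {
    top <- ranking$compound[1]
    def_lines <- names(sres$genotypes)[sres$genotypes == "deficient"]
    for (cl in def_lines) {
      ok <- tryCatch({
        m <- assemble_matrix(records, cl, top,
                             unique(records$compound_b[records$compound_b !=
                                                         "none"])[1],
                             replicate = min(records$replicate), size = size)
        plot_inhibition_heatmap(effect_matrix(m),
                                file = file.path(out_dir,
                                                 sprintf("heatmap_%s_%s.png",
                                                         top, cl)))
        TRUE
      }, error = function(e) FALSE)
      if (!ok) break
    }
  }

  manifest <- list(
    package = "synletscreen",
    package_version = as.character(utils::packageVersion("synletscreen")),
    seed = seed,
    parameters = list(value_kind = value_kind, aggregation_domain = domain,
                      grid_size = size),
    n_conditions_scored = nrow(sres$summaries),
    n_conditions_skipped = nrow(sres$qc),
    n_compounds_ranked = nrow(ranking),
    outputs = c(scores = scores_path, ranking = ranking_path, qc = qc_path))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(scores = sres$summaries, ranking = ranking, qc = sres$qc,
                 manifest = manifest))
}
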