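#' Score every condition of a combination screen
#'
#' Assembles one dose matrix per (cell line, compound pair, replicate) from
#' normalized records, computes the Bliss delta matrix and scalar score for
#' each, and summarizes replicates per condition. Conditions whose grid is
#' incomplete are skipped with a warning and recorded in the QC table, never
#' silently dropped.
#'
#' @param records Normalized plate records (combination wells; single-agent
#'   profiles with `compound_b == "none"` are ignored here).
#' @param domain Aggregation domain passed to [synergy_score()].
#' @param size Required grid size (see [assemble_matrix()]).
#' @return A `screen_result`: list with `summaries` (data.frame: cell_line,
#'   genotype, compound_a, compound_b, mean_score, sd_score, n_replicates),
#'   `qc` (skipped conditions with reasons) and `genotypes` (named vector).
#' @export
score_screen <- function(records, domain = "combinations_only", size = 6) {
  combo <- records[records$compound_b != "none", , drop = FALSE]
  if (nrow(combo) == 0) {
    stop("no combination records found", call. = FALSE)
  }
  conds <- unique(combo[, c("cell_line", "compound_a", "compound_b")])
  genotypes <- tapply(combo$genotype, combo$cell_line,
                      function(g) unique(g)[1])
  summaries <- NULL
  qc <- data.frame(cell_line = character(0), compound_a = character(0),
                   compound_b = character(0), replicate = integer(0),
                   reason = character(0))
  for (k in seq_len(nrow(conds))) {
    cl <- conds$cell_line[k]
    ca <- conds$compound_a[k]
    cb <- conds$compound_b[k]
    reps <- sort(unique(combo$replicate[combo$cell_line == cl &
                                          combo$compound_a == ca &
                                          combo$compound_b == cb]))
    results <- list()
    for (rep in reps) {
      res <- tryCatch({
        m <- assemble_matrix(combo, cl, ca, cb, replicate = rep, size = size)
        synergy_score(delta_matrix(effect_matrix(m)), domain = domain)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("condition %s/%s+%s replicate %d skipped: %s",
                        cl, ca, cb, rep, conditionMessage(res)),
                call. = FALSE)
        qc <- rbind(qc, data.frame(cell_line = cl, compound_a = ca,
                                   compound_b = cb, replicate = rep,
                                   reason = conditionMessage(res)))
      } else {
        results[[length(results) + 1]] <- res
      }
    }
    if (length(results) > 0) {
      s <- replicate_summary(results)
      summaries <- rbind(summaries, data.frame(
        cell_line = cl, genotype = unname(genotypes[cl]),
        compound_a = ca, compound_b = cb,
        mean_score = s$mean_score, sd_score = s$sd_score,
        n_replicates = s$n_replicates))
    }
  }
  rownames(summaries) <- NULL
  structure(list(summaries = summaries, qc = qc,
                 genotypes = unlist(genotypes)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: %d scored conditions, %d cell lines, %d skipped\n",
              nrow(x$summaries), length(x$genotypes), nrow(x$qc)))
  invisible(x)
}

#' Rank compounds by genotype-differential synergy
#'
#' For each library compound, averages the per-cell-line mean synergy scores
#' within each genotype (unweighted) and ranks compounds by the difference
#' deficient - proficient, descending. Ties break by the deficient mean,
#' then lexicographically by compound name. A compound is flagged a hit when
#' it carries the top difference and its deficient mean score exceeds 15.
#' Compounds missing a genotype entirely are excluded and reported.
#'
#' @param s A `screen_result` from [score_screen()].
#' @param deficient_label,proficient_label Genotype labels used in the
#'   records.
#' @return A `data.frame` (one row per ranked compound): compound,
#'   mean_deficient, mean_proficient, difference, rank, hit; attribute
#'   `excluded` lists compounds dropped for a missing genotype.
#' @export
genotype_difference_ranking <- function(s, deficient_label = "deficient",
                                        proficient_label = "proficient") {
  stopifnot(inherits(s, "screen_result"))
  sm <- s$summaries
  # the library compound is whichever side of the pair varies; with a fixed
  # anchor in compound_a the library compound is compound_b, and vice versa
  lib_col <- if (length(unique(sm$compound_a)) >=
                 length(unique(sm$compound_b))) "compound_a" else "compound_b"
  sm$compound <- sm[[lib_col]]
  compounds <- sort(unique(sm$compound))
  rows <- NULL
  excluded <- character(0)
  for (cmp in compounds) {
    sub <- sm[sm$compound == cmp, ]
    def <- sub$mean_score[sub$genotype == deficient_label]
    prof <- sub$mean_score[sub$genotype == proficient_label]
    if (length(def) == 0 || length(prof) == 0) {
      excluded <- c(excluded, cmp)
      next
    }
    rows <- rbind(rows, data.frame(
      compound = cmp, mean_deficient = mean(def),
      mean_proficient = mean(prof),
      difference = mean(def) - mean(prof)))
  }
  if (is.null(rows)) {
    stop("no compound has scores in both genotypes", call. = FALSE)
  }
  ord <- order(-rows$difference, -rows$mean_deficient, rows$compound)
  rows <- rows[ord, , drop = FALSE]
  rows$rank <- seq_len(nrow(rows))
  top_diff <- rows$difference[1]
  rows$hit <- rows$difference == top_diff & rows$mean_deficient > 15
  rownames(rows) <- NULL
  attr(rows, "excluded") <- excluded
  rows
}
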