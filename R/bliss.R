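#' Bliss-independence expected effect
#'
#' Expected combined inhibition of two agents acting independently:
#' `a + b - a * b`. Symmetric in its arguments; an effect of 1 is absorbing.
#'
#' @param alpha_a,alpha_b Single-agent inhibition fractions (vectorized).
#' @return Expected combined inhibition fraction(s).
#' @export
bliss_expected <- function(alpha_a, alpha_b) {
  if (!all(is.finite(alpha_a)) || !all(is.finite(alpha_b))) {
    stop("value error: non-finite effect passed to bliss_expected",
         call. = FALSE)
  }
  alpha_a + alpha_b - alpha_a * alpha_b
}

#' Delta-score matrix of a dose-combination grid
#'
#' For each cell of the grid, the excess of the observed inhibition over the
#' Bliss expectation computed from the matrix's own single-agent edges (the
#' row with compound B at 0 and the column with compound A at 0):
#' `delta[i, j] = effect[i, j] - bliss_expected(effect[i, 1], effect[1, j])`.
#' Vehicle and single-agent edge cells evaluate to 0 whenever the vehicle
#' cell's effect is 0.
#'
#' @param m A `combo_matrix` with the effect grid filled
#'   (see [effect_matrix()]).
#' @return A `synergy_result`: list with `delta` (matrix), `conc_a`,
#'   `conc_b`, `metadata`; `score`/`synergistic` are filled by
#'   [synergy_score()].
#' @export
delta_matrix <- function(m) {
  stopifnot(inherits(m, "combo_matrix"))
  if (is.null(m$effect)) {
    m <- effect_matrix(m)
  }
  eff <- m$effect
  if (anyNA(eff)) {
    stop("structural error: incomplete effect grid", call. = FALSE)
  }
  alpha_a <- eff[, 1]   # compound A alone (conc_b = 0 column)
  alpha_b <- eff[1, ]   # compound B alone (conc_a = 0 row)
  expected <- outer(alpha_a, alpha_b, bliss_expected)
  structure(list(delta = eff - expected, conc_a = m$conc_a, conc_b = m$conc_b,
                 score = NA_real_, synergistic = NA,
                 aggregation_domain = NA_character_,
                 metadata = m$metadata),
            class = "synergy_result")
}

#' Scalar synergy score of a delta matrix
#'
#' Aggregates the delta matrix to a single score in percentage points:
#' `100 * mean(delta)` over the aggregation domain. The default domain,
#' `"combinations_only"`, averages over the 25 cells where both
#' concentrations are positive; `"full_matrix"` includes the vehicle and
#' single-agent edges (whose deltas are 0 by construction, diluting a
#' constant-delta score by 25/36). A score strictly greater than 15 is
#' classified as synergistic.
#'
#' @param r A `synergy_result` from [delta_matrix()].
#' @param domain Aggregation domain.
#' @param threshold Classification threshold in percentage points.
#' @return The `synergy_result` with `score`, `synergistic` and
#'   `aggregation_domain` filled.
#' @export
synergy_score <- function(r, domain = c("combinations_only", "full_matrix"),
                          threshold = 15) {
  stopifnot(inherits(r, "synergy_result"))
  domain <- match.arg(domain)
  if (domain == "combinations_only") {
    cells <- r$delta[r$conc_a > 0, r$conc_b > 0, drop = FALSE]
  } else {
    cells <- r$delta
  }
  if (length(cells) == 0) {
    stop("structural error: empty aggregation domain", call. = FALSE)
  }
  r$score <- 100 * mean(cells)
  r$synergistic <- r$score > threshold
  r$aggregation_domain <- domain
  r
}

#' Summarize synergy scores over replicates
#'
#' Mean and sample standard deviation (n - 1 denominator) of per-replicate
#' scalar scores for one condition, matching the mean +/- SD presentation of
#' replicate synergy summaries. The SD is `NA` for a single replicate.
#'
#' @param results List of scored `synergy_result`s sharing cell line and
#'   compound pair (replicates of one condition).
#' @return List with `mean_score`, `sd_score`, `n_replicates`, `metadata`.
#' @export
replicate_summary <- function(results) {
  if (length(results) < 1) {
    stop("grouping error: need at least one replicate", call. = FALSE)
  }
  keys <- vapply(results, function(r) {
    paste(r$metadata$cell_line, r$metadata$compound_a, r$metadata$compound_b,
          sep = "|")
  }, character(1))
  if (length(unique(keys)) != 1) {
    stop("grouping error: replicates mix conditions: ",
         paste(unique(keys), collapse = " vs "), call. = FALSE)
  }
  scores <- vapply(results, function(r) r$score, numeric(1))
  if (anyNA(scores)) {
    stop("scores missing: run synergy_score() on every replicate first",
         call. = FALSE)
  }
  list(mean_score = mean(scores),
       sd_score = if (length(scores) > 1) sd(scores) else NA_real_,
       n_replicates = length(scores),
       metadata = results[[1]]$metadata)
}

#' @export
print.synergy_result <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("synergy_result: %s, %s x %s (replicate %s)\n",
              md$cell_line, md$compound_a, md$compound_b, md$replicate))
  if (!is.na(x$score)) {
    cat(sprintf("  score %.2f (%s), %s\n", x$score, x$aggregation_domain,
                if (isTRUE(x$synergistic)) "synergistic (> 15)" else
                  "not synergistic"))
  } else {
    cat("  delta matrix computed; score not aggregated yet\n")
  }
  invisible(x)
}

#' Heatmap of percent growth inhibition for a dose matrix
#'
#' Draws the 6x6 percent-inhibition surface with a red-green diverging map
#' (red = stronger inhibition, green = lower inhibition), optionally to a
#' PNG file.
#'
#' @param m A `combo_matrix` with effects filled.
#' @param file Optional PNG path; plots to the active device when `NULL`.
#' @return Invisibly, the percent-inhibition matrix drawn.
#' @export
plot_inhibition_heatmap <- function(m, file = NULL) {
  stopifnot(inherits(m, "combo_matrix"))
  if (is.null(m$effect)) m <- effect_matrix(m)
  pct <- 100 * m$effect
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 640)
    on.exit(grDevices::dev.off())
  }
  pal <- grDevices::colorRampPalette(c("#1a9641", "#ffffbf", "#d7191c"))(64)
  graphics::image(seq_along(m$conc_a), seq_along(m$conc_b), pct,
                  col = pal, zlim = c(0, 100), axes = FALSE,
                  xlab = paste(m$metadata$compound_a, "(uM)"),
                  ylab = paste(m$metadata$compound_b, "(uM)"),
                  main = sprintf("%s: %% growth inhibition",
                                 m$metadata$cell_line))
  graphics::axis(1, at = seq_along(m$conc_a), labels = signif(m$conc_a, 3))
  graphics::axis(2, at = seq_along(m$conc_b), labels = signif(m$conc_b, 3))
  for (i in seq_along(m$conc_a)) {
    for (j in seq_along(m$conc_b)) {
      graphics::text(i, j, sprintf("%.0f", pct[i, j]), cex = 0.8)
    }
  }
  invisible(pct)
}
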