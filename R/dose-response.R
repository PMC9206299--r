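#' Default single-agent concentration ladder
#'
#' Ten-point geometric series spanning 0.02-20 uM (step ~2.15x, i.e. an
#' approximately two-fold serial dilution). A strict two-fold series cannot
#' span this 1000-fold range in 10 points, so the series is geometric with
#' the stated endpoints fixed.
#'
#' @param n Number of points.
#' @param low,high Endpoints in uM.
#' @return Ascending concentration vector in uM.
#' @export
screen_concentrations <- function(n = 10, low = 0.02, high = 20) {
  exp(seq(log(low), log(high), length.out = n))
}

fpl <- function(conc, top, bottom, hill, ic50) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Fit a four-parameter logistic concentration-effect curve
#'
#' Fits `v(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill)` to a
#' single-agent viability profile by bounded least squares on
#' log10(concentration), with a small multi-start grid bracketing the
#' concentration range to avoid local minima. `hill > 0` gives the usual
#' decreasing viability curve.
#'
#' @param concentrations Strictly increasing positive concentrations (uM),
#'   at least 4 distinct values.
#' @param viability Viability fractions, one per concentration (replicates
#'   should be averaged first, or pass `replicate_matrix` rows yourself).
#' @param top_bounds,bottom_bounds Box constraints for the asymptotes.
#'   Defaults leave the top nearly fixed near 1 (`[0.8, 1.2]`) and the
#'   bottom free in `[0, 1]`.
#' @param fix_top,fix_bottom Optionally pin an asymptote to a value
#'   (e.g. `fix_top = 1`).
#' @return A `logistic_fit`: list with `top`, `bottom`, `hill`, `ic50`,
#'   `residual_sse`, `converged`, and `extrapolated` (TRUE when the fitted
#'   ic50 falls outside \[min conc / 10, max conc * 10\]).
#' @export
fit_logistic <- function(concentrations, viability,
                         top_bounds = c(0.8, 1.2), bottom_bounds = c(0, 1),
                         fix_top = NULL, fix_bottom = NULL) {
  ord <- order(concentrations)
  conc <- concentrations[ord]
  v <- viability[ord]
  if (length(unique(conc)) < 4) {
    stop("need at least 4 distinct concentrations to fit", call. = FALSE)
  }
  if (any(conc <= 0)) {
    stop("concentrations must be positive for log-scale fitting", call. = FALSE)
  }
  if (!all(is.finite(v))) {
    stop("viability values must be finite", call. = FALSE)
  }
  if (var(v) < 1e-12) {
    stop("degenerate-fit error: viability is constant across concentrations",
         call. = FALSE)
  }
  if (!is.null(fix_top)) top_bounds <- c(fix_top, fix_top)
  if (!is.null(fix_bottom)) bottom_bounds <- c(fix_bottom, fix_bottom)

  lconc <- log10(conc)
  dat <- data.frame(lc = lconc, v = v)
  # ic50 starts bracketing the observed range; hill start from the sign of
  # the overall trend
  trend <- if (v[length(v)] <= v[1]) 1 else -1
  lmid <- mean(range(lconc))
  starts <- list(
    c(lic50 = lmid, hill = trend),
    c(lic50 = quantile(lconc, 0.25, names = FALSE), hill = trend),
    c(lic50 = quantile(lconc, 0.75, names = FALSE), hill = trend)
  )
  clamp <- function(x, b) min(max(x, b[1]), b[2])
  best <- NULL
  best_par <- NULL
  for (s in starts) {
    start <- list(top = clamp(max(v), top_bounds),
                  bottom = clamp(min(v), bottom_bounds),
                  hill = s[["hill"]], lic50 = s[["lic50"]])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ bottom + (top - bottom) / (1 + 10^(hill * (lc - lic50))),
        data = dat, start = start,
        lower = c(top_bounds[1], bottom_bounds[1], -50,
                  min(lconc) - 3),
        upper = c(top_bounds[2], bottom_bounds[2], 50,
                  max(lconc) + 3),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(residuals(fit)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(sse = sse, conv = isTRUE(fit$convInfo$isConv))
      best_par <- coef(fit)
    }
  }
  # direct bounded least squares as a safety net: nlsLM can abort with a
  # singular Jacobian at the initial estimates on near-perfect data
  sse_fun <- function(p) {
    sum((v - (p[2] + (p[1] - p[2]) /
                (1 + 10^(p[3] * (lconc - p[4])))))^2)
  }
  for (s in starts) {
    op <- tryCatch(
      stats::optim(c(clamp(max(v), top_bounds),
                     clamp(min(v), bottom_bounds), s[["hill"]],
                     s[["lic50"]]),
                   sse_fun, method = "L-BFGS-B",
                   lower = c(top_bounds[1], bottom_bounds[1], -50,
                             min(lconc) - 3),
                   upper = c(top_bounds[2], bottom_bounds[2], 50,
                             max(lconc) + 3)),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$sse - 1e-12)) {
      best <- list(sse = op$value, conv = op$convergence == 0)
      best_par <- setNames(op$par, c("top", "bottom", "hill", "lic50"))
    }
  }
  if (is.null(best)) {
    return(structure(list(top = NA_real_, bottom = NA_real_, hill = NA_real_,
                          ic50 = NA_real_, residual_sse = NA_real_,
                          converged = FALSE, extrapolated = NA),
                     class = "logistic_fit"))
  }
  p <- best_par
  ic50_hat <- 10^p[["lic50"]]
  structure(list(
    top = p[["top"]], bottom = p[["bottom"]], hill = p[["hill"]],
    ic50 = ic50_hat, residual_sse = best$sse,
    converged = best$conv,
    extrapolated = ic50_hat < min(conc) / 10 || ic50_hat > max(conc) * 10),
    class = "logistic_fit")
}

#' Inhibitory concentration at a given viability level
#'
#' Inverts the fitted logistic curve: returns the concentration at which the
#' fitted viability equals `level`. With `top = 1`, `bottom = 0` and
#' `level = 0.5` this is the fit's `ic50` parameter.
#'
#' @param fit A converged `logistic_fit`.
#' @param level Target viability fraction, strictly between `bottom` and
#'   `top`.
#' @return Concentration in uM.
#' @export
ic50 <- function(fit, level = 0.5) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!isTRUE(fit$converged)) {
    stop("fit did not converge; no inhibitory concentration available",
         call. = FALSE)
  }
  lo <- min(fit$bottom, fit$top)
  hi <- max(fit$bottom, fit$top)
  if (level <= lo || level >= hi) {
    stop(sprintf(
      "out-of-range error: level %.3g outside the open interval (%.3g, %.3g)",
      level, lo, hi), call. = FALSE)
  }
  # level = bottom + (top - bottom)/(1 + (c/ic50)^hill)
  ratio <- (fit$top - level) / (level - fit$bottom)
  fit$ic50 * ratio^(1 / fit$hill)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("4PL concentration-effect fit\n")
  cat(sprintf("  top %.4g  bottom %.4g  hill %.4g  ic50 %.4g uM\n",
              x$top, x$bottom, x$hill, x$ic50))
  cat(sprintf("  SSE %.3g  converged %s%s\n", x$residual_sse, x$converged,
              if (isTRUE(x$extrapolated)) "  (ic50 extrapolated)" else ""))
  invisible(x)
}

#' Fit IC50s for every single-agent profile in a screen table
#'
#' Restricts records to `compound_b == "none"`, averages replicates per
#' concentration, and fits one logistic curve per (compound, cell line).
#'
#' @param records Normalized plate records (see [read_screen_table()]).
#' @param ... Passed to [fit_logistic()].
#' @return `data.frame` with one row per fit: compound, cell line, top,
#'   bottom, hill, ic50, sse, converged.
#' @export
fit_single_agents <- function(records, ...) {
  single <- records[records$compound_b == "none" & records$conc_a > 0, ,
                    drop = FALSE]
  if (nrow(single) == 0) {
    stop("no single-agent records (compound_b == 'none') found", call. = FALSE)
  }
  groups <- unique(single[, c("compound_a", "cell_line")])
  out <- NULL
  for (k in seq_len(nrow(groups))) {
    sub <- single[single$compound_a == groups$compound_a[k] &
                    single$cell_line == groups$cell_line[k], ]
    avg <- tapply(sub$value, sub$conc_a, mean)
    conc <- as.numeric(names(avg))
    fit <- fit_logistic(conc, as.numeric(avg), ...)
    out <- rbind(out, data.frame(
      compound = groups$compound_a[k], cell_line = groups$cell_line[k],
      top = fit$top, bottom = fit$bottom, hill = fit$hill, ic50 = fit$ic50,
      sse = fit$residual_sse, converged = fit$converged))
  }
  rownames(out) <- NULL
  out
}
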