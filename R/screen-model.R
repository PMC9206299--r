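#' @importFrom stats sd median var quantile coef residuals setNames
#' @importFrom utils read.csv read.delim write.table
NULL

SCREEN_COLUMNS <- c("cell_line", "genotype", "compound_a", "compound_b",
                    "conc_a", "conc_b", "replicate", "value")

#' Read a long-format plate screen table
#'
#' Reads a CSV/TSV table of per-well viability measurements with one row per
#' (cell line, compound A concentration, compound B concentration, replicate)
#' well. Concentrations are converted to micromolar using `conc_unit`.
#'
#' @param path Path to a delimited text file with header columns
#'   `cell_line`, `genotype`, `compound_a`, `compound_b`, `conc_a`, `conc_b`,
#'   `replicate`, `value`.
#' @param value_kind Whether `value` holds raw plate-reader intensities
#'   (`"raw"`) or viability fractions already normalized to vehicle
#'   (`"normalized"`).
#' @param conc_unit Unit of the concentration columns in the file; one of
#'   `"uM"`, `"nM"`, `"mM"`. Values are converted to uM.
#' @param sep Field separator; guessed from the file extension when `NULL`.
#' @return A `data.frame` of plate records (concentrations in uM) with
#'   attribute `value_kind`.
#' @export
read_screen_table <- function(path, value_kind = c("normalized", "raw"),
                              conc_unit = c("uM", "nM", "mM"), sep = NULL) {
  value_kind <- match.arg(value_kind)
  conc_unit <- match.arg(conc_unit)
  if (!file.exists(path)) {
    stop("screen table not found: ", path, call. = FALSE)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(SCREEN_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rec <- raw[, SCREEN_COLUMNS]
  for (col in c("conc_a", "conc_b", "replicate", "value")) {
    num <- suppressWarnings(as.numeric(rec[[col]]))
    bad <- which(is.na(num) & !is.na(rec[[col]]) & nzchar(rec[[col]]))
    if (length(bad) > 0 || anyNA(num)) {
      row <- if (length(bad) > 0) bad[1] else which(is.na(num))[1]
      stop(sprintf("parse error: non-numeric '%s' in column '%s' at data row %d",
                   rec[[col]][row], col, row), call. = FALSE)
    }
    rec[[col]] <- num
  }
  scale <- c(uM = 1, nM = 1e-3, mM = 1e3)[[conc_unit]]
  rec$conc_a <- rec$conc_a * scale
  rec$conc_b <- rec$conc_b * scale
  validate_screen_records(rec)
  attr(rec, "value_kind") <- value_kind
  rec
}

validate_screen_records <- function(rec) {
  if (any(rec$conc_a < 0) || any(rec$conc_b < 0)) {
    stop("invalid record: negative concentration", call. = FALSE)
  }
  if (any(rec$value < 0)) {
    stop("invalid record: negative value", call. = FALSE)
  }
  if (any(rec$replicate < 1 | rec$replicate != round(rec$replicate))) {
    stop("invalid record: replicate must be a positive integer", call. = FALSE)
  }
  key <- with(rec, paste(cell_line, compound_a, compound_b,
                         conc_a, conc_b, replicate, sep = "|"))
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    stop("duplication error: duplicate well key(s): ",
         paste(unique(dup), collapse = "; "), call. = FALSE)
  }
  invisible(rec)
}

#' Write plate records back to a long-format CSV
#'
#' Inverse of [read_screen_table()]; the written file re-reads to identical
#' records (concentrations written in uM).
#'
#' @param records Plate-record `data.frame`.
#' @param path Output file path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(records, path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  out <- records[, SCREEN_COLUMNS]
  for (col in c("conc_a", "conc_b", "value")) {
    out[[col]] <- sprintf("%.17g", out[[col]])  # lossless numeric round trip
  }
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize raw viability reads to vehicle control wells
#'
#' Each well's value is divided by the arithmetic mean of the vehicle wells
#' (both concentrations zero) of its (cell line, compound pair, replicate)
#' group, so vehicle wells average to 1. Values above 1 (growth stimulation)
#' are retained.
#'
#' @param records Plate-record `data.frame` (raw or already normalized;
#'   normalization is idempotent on normalized groups).
#' @return Records with `value` rescaled and attribute `value_kind =
#'   "normalized"`; attribute `norm_factors` holds the per-group vehicle
#'   means applied.
#' @export
normalize_viability <- function(records) {
  grp <- with(records, interaction(cell_line, compound_a, compound_b,
                                   replicate, drop = TRUE, lex.order = TRUE))
  out <- records
  factors <- data.frame(group = character(0), vehicle_mean = numeric(0))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    veh <- idx[records$conc_a[idx] == 0 & records$conc_b[idx] == 0]
    if (length(veh) == 0) {
      stop("normalization error: no vehicle well in group ", g, call. = FALSE)
    }
    m <- mean(records$value[veh])
    if (m == 0) {
      stop("degenerate-control error: vehicle mean is 0 in group ", g,
           call. = FALSE)
    }
    out$value[idx] <- records$value[idx] / m
    factors <- rbind(factors, data.frame(group = g, vehicle_mean = m))
  }
  attr(out, "value_kind") <- "normalized"
  attr(out, "norm_factors") <- factors
  out
}

#' Assemble one dose-combination matrix from plate records
#'
#' Collects the wells of one (cell line, compound pair, replicate) condition
#' into a complete dose grid: rows are compound A concentrations (ascending,
#' first = 0 vehicle), columns compound B concentrations. The default design
#' is 6x6 (vehicle + 5 concentrations per agent, 25 combinations).
#'
#' @param records Normalized plate records.
#' @param cell_line,compound_a,compound_b Condition selectors.
#' @param replicate Replicate number.
#' @param size Required grid side length (`NA` to accept any complete grid).
#' @return A `combo_matrix`: list with `conc_a`, `conc_b`, `viability`
#'   (matrix, rows = conc_a), `effect` (filled by [effect_matrix()]) and
#'   `metadata`.
#' @export
assemble_matrix <- function(records, cell_line, compound_a, compound_b,
                            replicate = 1, size = 6) {
  sel <- records$cell_line == cell_line &
    records$compound_a == compound_a &
    records$compound_b == compound_b &
    records$replicate == replicate
  sub <- records[sel, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("structural error: no records for condition ", cell_line, "/",
         compound_a, "+", compound_b, " replicate ", replicate, call. = FALSE)
  }
  ca <- sort(unique(sub$conc_a))
  cb <- sort(unique(sub$conc_b))
  if (!is.na(size) && (length(ca) != size || length(cb) != size)) {
    stop(sprintf("structural error: expected %dx%d grid, found %dx%d axes",
                 size, size, length(ca), length(cb)), call. = FALSE)
  }
  if (ca[1] != 0 || cb[1] != 0) {
    stop("structural error: vehicle concentration 0 missing from an axis",
         call. = FALSE)
  }
  v <- matrix(NA_real_, length(ca), length(cb),
              dimnames = list(conc_a = ca, conc_b = cb))
  i <- match(sub$conc_a, ca)
  j <- match(sub$conc_b, cb)
  v[cbind(i, j)] <- sub$value
  if (anyNA(v)) {
    miss <- which(is.na(v), arr.ind = TRUE)
    stop(sprintf("incomplete grid: %d missing cell(s), first at conc_a=%g, conc_b=%g",
                 nrow(miss), ca[miss[1, 1]], cb[miss[1, 2]]), call. = FALSE)
  }
  genotype <- unique(sub$genotype)
  structure(list(conc_a = ca, conc_b = cb, viability = v, effect = NULL,
                 metadata = list(cell_line = cell_line, genotype = genotype,
                                 compound_a = compound_a,
                                 compound_b = compound_b,
                                 replicate = replicate)),
            class = "combo_matrix")
}

#' Convert viability to inhibition effects
#'
#' Fills the `effect` grid of a combination matrix as `1 - viability`. With
#' `clip = TRUE` (default) effects are bounded to \[0, 1\] so they behave as
#' probabilities under the Bliss composition; unclipped effects keep
#' `effect + viability = 1` exactly (viability above 1 maps to a negative
#' effect).
#'
#' @param m A `combo_matrix` with a complete viability grid.
#' @param clip Bound effects to \[0, 1\]?
#' @return The matrix with `effect` filled.
#' @export
effect_matrix <- function(m, clip = TRUE) {
  stopifnot(inherits(m, "combo_matrix"))
  if (is.null(m$viability) || anyNA(m$viability)) {
    stop("structural error: incomplete viability grid", call. = FALSE)
  }
  eff <- 1 - m$viability
  if (clip) {
    eff <- pmin(pmax(eff, 0), 1)
  }
  m$effect <- eff
  m$clipped <- clip
  m
}

#' @export
print.combo_matrix <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("combo_matrix: %s (%s), %s x %s, replicate %s\n",
              md$cell_line, paste(md$genotype, collapse = "/"),
              md$compound_a, md$compound_b, md$replicate))
  cat(sprintf("  %d x %d grid; conc_a (uM): %s; conc_b (uM): %s\n",
              nrow(x$viability), ncol(x$viability),
              paste(signif(x$conc_a, 3), collapse = ", "),
              paste(signif(x$conc_b, 3), collapse = ", ")))
  cat(sprintf("  effect grid: %s\n",
              if (is.null(x$effect)) "not computed" else "computed"))
  invisible(x)
}
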