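with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) {
    stop("spec error: a seed is mandatory for every generator", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic combination screen
#'
#' Describes the design of a plate-based combination screen: a cell-line
#' panel with genotype labels, a compound library combined against a fixed
#' anchor compound, per-agent 5-point two-fold concentration ladders,
#' logistic single-agent potencies, an injected-synergy map and a viability
#' noise level. The defaults mirror a 4-cell-line (2 per genotype),
#' 27-compound screen on 6x6 grids.
#'
#' Single-agent potencies default to an IC50 of twice the top ladder
#' concentration (hill 1), keeping the multiplicative Bliss-null surface
#' well above zero so an injected delta up to ~0.4 survives the viability
#' floor unclipped.
#'
#' @param cell_lines,genotypes Parallel vectors of line names and labels in
#'   `{deficient, proficient}`.
#' @param compounds Library compound names.
#' @param anchor Anchor compound name (combined with every library
#'   compound).
#' @param conc,anchor_conc 5-point ascending positive concentration ladders
#'   (uM) for library compounds and the anchor.
#' @param ic50_compound,ic50_anchor,hill Logistic potency parameters shared
#'   across the panel (top 1, bottom 0).
#' @param injected `data.frame(compound, genotype, delta)` of synergy to
#'   inject: delta is added to the inhibition of every combination cell of
#'   matching conditions. `NULL` for a pure Bliss-null screen.
#' @param sigma Gaussian viability noise SD (additive, truncated at 0).
#' @param replicates Replicates per condition.
#' @param seed Mandatory RNG seed.
#' @return A `screen_spec` list.
#' @export
screen_spec <- function(cell_lines = c("KB1P-G3", "KB1P-B11",
                                       "KP-3.33", "KP-6.3"),
                        genotypes = c("deficient", "deficient",
                                      "proficient", "proficient"),
                        compounds = sprintf("compound%02d", 1:27),
                        anchor = "GSK126",
                        conc = c(0.625, 1.25, 2.5, 5, 10),
                        anchor_conc = conc,
                        ic50_compound = 20, ic50_anchor = 20, hill = 1,
                        injected = NULL, sigma = 0.05, replicates = 1,
                        seed = NULL) {
  stopifnot(length(cell_lines) == length(genotypes),
            all(genotypes %in% c("deficient", "proficient")),
            all(conc > 0), all(diff(conc) > 0),
            all(anchor_conc > 0), all(diff(anchor_conc) > 0))
  if (sigma < 0) stop("spec error: sigma must be >= 0", call. = FALSE)
  if (!is.null(injected)) {
    stopifnot(all(c("compound", "genotype", "delta") %in% names(injected)))
    if (any(abs(injected$delta) > 1)) {
      stop("spec error: injected delta must lie in [-1, 1]", call. = FALSE)
    }
  }
  if (is.null(seed)) {
    stop("spec error: a seed is mandatory", call. = FALSE)
  }
  structure(list(cell_lines = cell_lines, genotypes = genotypes,
                 compounds = compounds, anchor = anchor, conc = conc,
                 anchor_conc = anchor_conc, ic50_compound = ic50_compound,
                 ic50_anchor = ic50_anchor, hill = hill, injected = injected,
                 sigma = sigma, replicates = replicates, seed = seed),
            class = "screen_spec")
}

#' Generate a normalized combination screen
#'
#' Simulates every (cell line, library compound, replicate) 6x6 matrix of
#' the spec under a multiplicative Bliss-null viability surface:
#' `v[i, j] = v_a[i] * v_b[j] - delta * 1[i > 0, j > 0] + noise`, truncated
#' at 0, with single-agent viabilities from the spec's logistic potencies
#' and the vehicle cell at `1 + noise`. Deterministic for a fixed seed.
#'
#' @param spec A [screen_spec()].
#' @return Long-format normalized plate records (library compound in
#'   `compound_a`, anchor in `compound_b`).
#' @export
gen_screen <- function(spec) {
  stopifnot(inherits(spec, "screen_spec"))
  with_seed(spec$seed, {
    ca <- c(0, spec$conc)
    cb <- c(0, spec$anchor_conc)
    v_a <- c(1, 1 / (1 + (spec$conc / spec$ic50_compound)^spec$hill))
    v_b <- c(1, 1 / (1 + (spec$anchor_conc / spec$ic50_anchor)^spec$hill))
    grid <- expand.grid(conc_a = seq_along(ca), conc_b = seq_along(cb),
                        replicate = seq_len(spec$replicates),
                        compound = spec$compounds,
                        line = seq_along(spec$cell_lines),
                        stringsAsFactors = FALSE)
    v_null <- v_a[grid$conc_a] * v_b[grid$conc_b]
    delta <- numeric(nrow(grid))
    if (!is.null(spec$injected)) {
      geno <- spec$genotypes[grid$line]
      for (k in seq_len(nrow(spec$injected))) {
        sel <- grid$compound == spec$injected$compound[k] &
          geno == spec$injected$genotype[k] &
          grid$conc_a > 1 & grid$conc_b > 1
        delta[sel] <- delta[sel] + spec$injected$delta[k]
      }
    }
    v <- v_null - delta
    if (spec$sigma > 0) {
      v <- v + stats::rnorm(length(v), 0, spec$sigma)
    }
    v <- pmax(v, 0)
    data.frame(cell_line = spec$cell_lines[grid$line],
               genotype = spec$genotypes[grid$line],
               compound_a = grid$compound,
               compound_b = spec$anchor,
               conc_a = ca[grid$conc_a],
               conc_b = cb[grid$conc_b],
               replicate = grid$replicate,
               value = v,
               stringsAsFactors = FALSE)
  })
}

#' Generate a single-agent dose-response profile
#'
#' Samples a 4PL viability curve at a concentration ladder with optional
#' Gaussian noise.
#'
#' @param top,bottom,hill,ic50 Curve parameters (`hill != 0`; positive hill
#'   = decreasing viability).
#' @param concentrations Ladder in uM (default the 10-point 0.02-20 uM
#'   screen series).
#' @param sigma Gaussian noise SD on viability.
#' @param seed Mandatory RNG seed.
#' @return List with `concentrations`, `viability` and the true parameters.
#' @export
gen_dose_response_curve <- function(top = 1, bottom = 0, hill = 1, ic50,
                                    concentrations = screen_concentrations(),
                                    sigma = 0, seed = NULL) {
  if (hill == 0) stop("hill must be nonzero", call. = FALSE)
  with_seed(seed, {
    v <- fpl(concentrations, top, bottom, hill, ic50)
    if (sigma > 0) v <- v + stats::rnorm(length(v), 0, sigma)
    list(concentrations = concentrations, viability = v,
         truth = list(top = top, bottom = bottom, hill = hill, ic50 = ic50))
  })
}

place_discs <- function(n, radius_px, dim_px, margin, min_sep, max_tries = 5000) {
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(centers) < n && tries < max_tries) {
    tries <- tries + 1
    cand <- stats::runif(2, margin + radius_px, dim_px - margin - radius_px)
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                           byrow = TRUE))^2)) >= min_sep)) {
      centers <- rbind(centers, cand)
    }
  }
  if (nrow(centers) < n) {
    stop("could not place ", n, " non-overlapping nuclei; reduce n or radius",
         call. = FALSE)
  }
  centers
}

draw_disc <- function(img, cx, cy, r, value, add = FALSE) {
  x0 <- max(1, floor(cx - r - 1)); x1 <- min(nrow(img), ceiling(cx + r + 1))
  y0 <- max(1, floor(cy - r - 1)); y1 <- min(ncol(img), ceiling(cy + r + 1))
  xs <- x0:x1; ys <- y0:y1
  d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
  inside <- d2 <= r^2
  patch <- img[xs, ys]
  patch[inside] <- if (add) patch[inside] + value else value
  img[xs, ys] <- patch
  img
}

#' Generate a synthetic two-channel foci field with ground truth
#'
#' Draws non-overlapping disc nuclei in the nuclear channel and plants
#' point-like foci (small discs) inside each nucleus in the foci channel,
#' with optional Gaussian noise at a chosen signal-to-noise ratio. Objects
#' deliberately violating the default filters can be planted and appear in
#' the ground truth flagged `filtered`.
#'
#' @param n_nuclei Nuclei to place.
#' @param foci_per_nucleus Foci planted per nucleus (scalar or vector).
#' @param dim_px Square field side in pixels.
#' @param pixel_size um per pixel.
#' @param nucleus_radius_um,focus_radius_um Object radii.
#' @param nucleus_intensity,focus_amplitude Intensities (a.u.); defaults sit
#'   inside the default filter windows.
#' @param snr Signal-to-noise ratio; `Inf` for a noiseless field (noise SD =
#'   amplitude / snr per channel, truncated at 0).
#' @param background Constant background offset added to both channels.
#' @param gradient Peak-to-corner amplitude of a planar illumination
#'   gradient added to both channels (exercises background correction).
#' @param plant_undersized_nucleus Also place one ~50 um^2 nucleus (fails
#'   the 100-1500 um^2 filter).
#' @param plant_oversized_focus Also plant one ~40 um^2 focus in the first
#'   nucleus (fails the 1-30 um^2 filter).
#' @param condition,field_id Identifiers for the resulting `foci_image`.
#' @param seed Mandatory RNG seed.
#' @return List with `image` (a `foci_image`) and `truth` (list of `nuclei`
#'   and `foci` data.frames; filter-violating plants carry
#'   `filtered = TRUE`).
#' @export
gen_foci_image <- function(n_nuclei = 5, foci_per_nucleus = 3, dim_px = 256,
                           pixel_size = 0.65, nucleus_radius_um = 11.3,
                           focus_radius_um = 1.1,
                           nucleus_intensity = 2000, focus_amplitude = 4000,
                           snr = Inf, background = 0, gradient = 0,
                           plant_undersized_nucleus = FALSE,
                           plant_oversized_focus = FALSE,
                           condition = "untreated", field_id = "field1",
                           seed = NULL) {
  with_seed(seed, {
    r_px <- nucleus_radius_um / pixel_size
    fr_px <- focus_radius_um / pixel_size
    k <- rep_len(foci_per_nucleus, n_nuclei)
    extra <- as.integer(plant_undersized_nucleus)
    centers <- place_discs(n_nuclei + extra, r_px, dim_px,
                           margin = 4, min_sep = 2 * r_px + 6)
    nuc <- matrix(0, dim_px, dim_px)
    foc <- matrix(0, dim_px, dim_px)
    truth_nuclei <- NULL
    truth_foci <- NULL
    for (i in seq_len(n_nuclei)) {
      nuc <- draw_disc(nuc, centers[i, 1], centers[i, 2], r_px,
                       nucleus_intensity)
      truth_nuclei <- rbind(truth_nuclei, data.frame(
        nucleus = i, cx = centers[i, 1], cy = centers[i, 2],
        radius_um = nucleus_radius_um,
        area_um2 = pi * nucleus_radius_um^2, filtered = FALSE))
      n_f <- k[i]
      if (n_f > 0) {
        # distinct sites: rejection-sample focus centers with a minimum
        # separation so planted foci resolve as separate spots
        min_sep <- 3.3 * fr_px + 1
        placed <- matrix(numeric(0), 0, 2)
        tries <- 0
        while (nrow(placed) < n_f && tries < 20000) {
          tries <- tries + 1
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- sqrt(stats::runif(1)) * 0.85 * r_px
          cand <- centers[i, ] + rad * c(cos(ang), sin(ang))
          if (nrow(placed) == 0 ||
              all(sqrt(rowSums((placed - matrix(cand, nrow(placed), 2,
                                                byrow = TRUE))^2)) >=
                    min_sep)) {
            placed <- rbind(placed, cand)
          }
        }
        if (nrow(placed) < n_f) {
          stop("could not place ", n_f, " separated foci in one nucleus",
               call. = FALSE)
        }
        for (j in seq_len(n_f)) {
          foc <- draw_disc(foc, placed[j, 1], placed[j, 2], fr_px,
                           focus_amplitude, add = TRUE)
          truth_foci <- rbind(truth_foci, data.frame(
            nucleus = i, cx = placed[j, 1], cy = placed[j, 2],
            radius_um = focus_radius_um, filtered = FALSE))
        }
      }
    }
    if (plant_undersized_nucleus) {
      i <- n_nuclei + 1
      small_r_um <- sqrt(50 / pi)  # ~50 um^2, below the 100 um^2 bound
      nuc <- draw_disc(nuc, centers[i, 1], centers[i, 2],
                       small_r_um / pixel_size, nucleus_intensity)
      truth_nuclei <- rbind(truth_nuclei, data.frame(
        nucleus = i, cx = centers[i, 1], cy = centers[i, 2],
        radius_um = small_r_um, area_um2 = 50, filtered = TRUE))
    }
    if (plant_oversized_focus) {
      big_r_um <- sqrt(40 / pi)  # ~40 um^2, above the 30 um^2 bound
      fx <- centers[1, 1]
      fy <- centers[1, 2]
      foc <- draw_disc(foc, fx, fy, big_r_um / pixel_size, focus_amplitude,
                       add = TRUE)
      truth_foci <- rbind(truth_foci, data.frame(
        nucleus = 1, cx = fx, cy = fy, radius_um = big_r_um, filtered = TRUE))
    }
    if (background > 0) {
      nuc <- nuc + background
      foc <- foc + background
    }
    if (gradient > 0) {
      ramp <- outer(seq(0, 1, length.out = dim_px),
                    seq(0, 1, length.out = dim_px), "+") / 2
      nuc <- nuc + gradient * ramp
      foc <- foc + gradient * ramp
    }
    if (is.finite(snr)) {
      nuc <- pmax(nuc + stats::rnorm(length(nuc), 0,
                                     nucleus_intensity / snr), 0)
      foc <- pmax(foc + stats::rnorm(length(foc), 0,
                                     focus_amplitude / snr), 0)
    }
    list(image = foci_image(nuc, foc, pixel_size = pixel_size,
                            field_id = field_id, condition = condition),
         truth = list(nuclei = truth_nuclei,
                      foci = if (is.null(truth_foci)) {
                        data.frame(nucleus = integer(0), cx = numeric(0),
                                   cy = numeric(0), radius_um = numeric(0),
                                   filtered = logical(0))
                      } else {
                        truth_foci
                      }))
  })
}

#' Generate per-animal tumor growth trajectories
#'
#' Exponential growth from a ~100 mm^3 implant with per-arm growth rates
#' and multiplicative lognormal measurement noise, rendered as caliper
#' (length, width) pairs with length >= width. Measurements follow a
#' twice-weekly schedule.
#'
#' @param n_per_arm Animals per arm.
#' @param growth_rates Named numeric vector of per-day exponential growth
#'   rates, one per arm. Defaults approximate a vehicle arm progressing
#'   (10x volume) near day 21 and a combination arm near day 40.
#' @param days Measurement days (default twice weekly to day 59).
#' @param v0 Day-0 volume in mm^3.
#' @param sdlog Lognormal measurement noise SD (log scale).
#' @param censor `data.frame(arm, index, day)` of animals removed early
#'   (censored at `day`), or `NULL`.
#' @param seed Mandatory RNG seed.
#' @return List of `tumor_trajectory` objects.
#' @export
gen_growth_trajectories <- function(n_per_arm = 7,
                                    growth_rates = c(vehicle = log(10) / 21,
                                                     combination = log(10) / 40),
                                    days = c(0, 3, 7, 10, 14, 17, 21, 24, 28,
                                             31, 35, 38, 42, 45, 49, 52, 56, 59),
                                    v0 = 100, sdlog = 0.1, censor = NULL,
                                    seed = NULL) {
  stopifnot(!is.null(names(growth_rates)))
  with_seed(seed, {
    out <- list()
    for (arm in names(growth_rates)) {
      r <- growth_rates[[arm]]
      for (i in seq_len(n_per_arm)) {
        noise <- if (sdlog > 0) {
          stats::rlnorm(length(days), 0, sdlog)
        } else {
          rep(1, length(days))
        }
        noise[days == 0] <- 1  # RTV anchored at the day-0 measurement
        vol <- v0 * exp(r * days) * noise
        aspect <- stats::runif(1, 1, 1.4)
        width <- (2 * vol / aspect)^(1 / 3)
        length_ <- aspect * width
        id <- paste0(arm, "-", i)
        censored <- FALSE
        censor_day <- NA
        if (!is.null(censor)) {
          hit <- censor$arm == arm & censor$index == i
          if (any(hit)) {
            censored <- TRUE
            censor_day <- censor$day[which(hit)[1]]
          }
        }
        out[[id]] <- tumor_trajectory(id, arm, days, length_, width,
                                      censored = censored,
                                      censor_day = censor_day)
      }
    }
    out
  })
}
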