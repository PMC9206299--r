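#' Tumor volume from caliper length and width
#'
#' `0.5 * length * width^2` in mm^3. By caliper convention length is the
#' longer axis; swapped inputs are corrected with a warning.
#'
#' @param length,width Caliper measurements in mm (vectorized).
#' @return Volume(s) in mm^3.
#' @export
caliper_volume <- function(length, width) {
  if (any(length <= 0) || any(width <= 0)) {
    stop("caliper measurements must be positive", call. = FALSE)
  }
  swap <- width > length
  if (any(swap)) {
    warning("width > length for ", sum(swap),
            " measurement(s); axes swapped (caliper convention)")
    tmp <- length[swap]
    length[swap] <- width[swap]
    width[swap] <- tmp
  }
  0.5 * length * width^2
}

#' Construct a per-animal tumor growth trajectory
#'
#' @param animal Animal identifier.
#' @param arm Treatment arm label.
#' @param day Measurement days (integers, strictly increasing, day 0 =
#'   treatment start present).
#' @param length,width Caliper measurements in mm, one per day.
#' @param censored Logical: was the animal removed for a non-progression
#'   reason (found dead, open tumor)?
#' @param censor_day Removal day when `censored`.
#' @param censor_reason Free-text reason.
#' @return A `tumor_trajectory`.
#' @export
tumor_trajectory <- function(animal, arm, day, length, width,
                             censored = FALSE, censor_day = NA,
                             censor_reason = NA_character_) {
  if (any(diff(day) <= 0)) {
    stop("days must be strictly increasing", call. = FALSE)
  }
  if (!0 %in% day) {
    stop("endpoint error: day-0 (treatment start) measurement missing",
         call. = FALSE)
  }
  if (any(width > length)) {
    stop("length must be >= width in a trajectory; use caliper_volume() to swap",
         call. = FALSE)
  }
  structure(list(animal = animal, arm = arm, day = day, length = length,
                 width = width, censored = censored, censor_day = censor_day,
                 censor_reason = censor_reason),
            class = "tumor_trajectory")
}

#' Relative tumor volume series
#'
#' Volumes normalized to the day-0 (treatment start) volume; RTV(0) = 1.
#'
#' @param t A `tumor_trajectory`.
#' @return `data.frame` with columns `day`, `volume` (mm^3), `rtv`.
#' @export
rtv_series <- function(t) {
  stopifnot(inherits(t, "tumor_trajectory"))
  vol <- caliper_volume(t$length, t$width)
  v0 <- vol[t$day == 0]
  if (length(v0) != 1) {
    stop("endpoint error: day-0 measurement missing", call. = FALSE)
  }
  if (v0 == 0) {
    stop("degenerate error: day-0 volume is zero", call. = FALSE)
  }
  data.frame(day = t$day, volume = vol, rtv = vol / v0)
}

#' Progression event from an RTV threshold
#'
#' Progression-free survival time is the first measurement day at which the
#' relative tumor volume reaches `threshold` (default 10-fold); no
#' interpolation between visits. A trajectory that never crosses is censored
#' at its last measurement day; an animal removed early (censored flag) is
#' censored at its removal day.
#'
#' @param t A `tumor_trajectory`.
#' @param threshold RTV defining progression.
#' @return `data.frame` row: animal, arm, time (days), event (1 =
#'   progression, 0 = censored).
#' @export
pfs_event <- function(t, threshold = 10) {
  stopifnot(inherits(t, "tumor_trajectory"))
  rtv <- rtv_series(t)
  if (isTRUE(t$censored)) {
    time <- if (is.na(t$censor_day)) max(rtv$day) else t$censor_day
    obs <- rtv[rtv$day <= time, , drop = FALSE]
    cross <- which(obs$rtv >= threshold & obs$day > 0)
    if (length(cross) > 0) {
      return(data.frame(animal = t$animal, arm = t$arm,
                        time = obs$day[cross[1]], event = 1L))
    }
    return(data.frame(animal = t$animal, arm = t$arm, time = time,
                      event = 0L))
  }
  cross <- which(rtv$rtv >= threshold & rtv$day > 0)
  if (length(cross) > 0) {
    data.frame(animal = t$animal, arm = t$arm, time = rtv$day[cross[1]],
               event = 1L)
  } else {
    data.frame(animal = t$animal, arm = t$arm, time = max(rtv$day),
               event = 0L)
  }
}

#' Kaplan-Meier curves and log-rank comparison of two arms
#'
#' Product-limit survival estimate per arm and the unweighted (Mantel-Cox)
#' two-sample log-rank test.
#'
#' With few animals the chi-square reference distribution is a coarse
#' approximation: the permutation null of a 3-vs-3 comparison has only 20
#' support points. `p_method = "permutation"` estimates the exact p-value
#' by Monte-Carlo label permutation of the same statistic instead.
#'
#' @param records `data.frame` of survival records (columns `animal`, `arm`,
#'   `time`, `event`), e.g. rows from [pfs_event()].
#' @param arms Character vector of two arm labels to compare.
#' @param p_method `"asymptotic"` (chi-square) or `"permutation"`.
#' @param n_perm,perm_seed Permutation count and seed for
#'   `p_method = "permutation"`.
#' @return List with `fit` (a `survival::survfit` object), `chisq`, `df`,
#'   `p`, `p_method`.
#' @export
km_logrank <- function(records, arms = unique(records$arm),
                       p_method = c("asymptotic", "permutation"),
                       n_perm = 10000, perm_seed = 1) {
  p_method <- match.arg(p_method)
  if (length(arms) != 2) {
    stop("km_logrank compares exactly two arms", call. = FALSE)
  }
  sub <- records[records$arm %in% arms, , drop = FALSE]
  for (a in arms) {
    if (sum(sub$arm == a) == 0) {
      stop("grouping error: arm '", a, "' has no records", call. = FALSE)
    }
  }
  sub$arm <- factor(sub$arm, levels = arms)
  fit <- survival::survfit(survival::Surv(time, event) ~ arm, data = sub)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ arm, data = sub,
                            rho = 0)
  df <- length(sd_$n) - 1
  if (p_method == "asymptotic") {
    p <- stats::pchisq(sd_$chisq, df = df, lower.tail = FALSE)
  } else {
    p <- with_seed(perm_seed, {
      obs <- sd_$chisq
      hits <- 0
      for (b in seq_len(n_perm)) {
        perm <- sub
        perm$arm <- sample(perm$arm)
        chi_b <- tryCatch(
          survival::survdiff(survival::Surv(time, event) ~ arm, data = perm,
                             rho = 0)$chisq,
          error = function(e) 0)
        if (chi_b >= obs - 1e-12) hits <- hits + 1
      }
      hits / n_perm
    })
  }
  list(fit = fit, chisq = unname(sd_$chisq), df = df, p = unname(p),
       p_method = p_method)
}

#' Read caliper measurement tables into trajectories
#'
#' @param path CSV with columns `animal`, `arm`, `day`, `length_mm`,
#'   `width_mm` and optionally `censor_flag`, `censor_day`.
#' @return List of `tumor_trajectory` objects.
#' @export
read_caliper_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "arm", "day", "length_mm", "width_mm")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lapply(split(tab, tab$animal), function(sub) {
    sub <- sub[order(sub$day), ]
    censored <- "censor_flag" %in% names(sub) && any(sub$censor_flag %in%
                                                      c(1, TRUE, "TRUE"))
    censor_day <- if (censored && "censor_day" %in% names(sub)) {
      sub$censor_day[1]
    } else {
      NA
    }
    tumor_trajectory(sub$animal[1], sub$arm[1], sub$day, sub$length_mm,
                     sub$width_mm, censored = censored,
                     censor_day = censor_day)
  })
}
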