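#' Two-parameter Box-Cox transform parameters
#'
#' Raw IPDs are roughly exponentially distributed; a power transform with an
#' optional additive pre-shift brings them close to normal so that the
#' downstream normal-theory hierarchical model applies. The transform is
#' `y = ((x + shift)^lam - 1) / lam` for `lam != 0` and `y = log(x + shift)`
#' in the `lam -> 0` limit. Both parameters are chemistry-specific and are
#' either supplied explicitly or estimated by [calibrate_transform()].
#'
#' @param lam dimensionless exponent; finite; 0 means the logarithm limit
#' @param shift additive offset in seconds applied before exponentiation;
#'   must be >= 0
#' @param median_skewness optional diagnostic recorded by the calibration
#' @return a `transform_params` object
#' @export
transform_params <- function(lam, shift = 0, median_skewness = NA_real_) {
  stopifnot(is.finite(lam), is.numeric(shift), shift >= 0)
  structure(list(lam = lam, shift = shift, median_skewness = median_skewness),
            class = "transform_params")
}

#' @export
print.transform_params <- function(x, ...) {
  cat(sprintf("<transform_params> lam=%.4g shift=%.4g", x$lam, x$shift))
  if (is.finite(x$median_skewness))
    cat(sprintf("  (median position skewness at calibration: %.4f)",
                x$median_skewness))
  cat("\n")
  invisible(x)
}

#' Box-Cox transform a vector of raw IPDs
#'
#' Strictly monotone for any valid parameters, so observation ranks are
#' preserved.
#'
#' @param ipds positive numeric vector (seconds)
#' @param params a [transform_params()]
#' @return transformed values
#' @export
boxcox_transform <- function(ipds, params) {
  stopifnot(inherits(params, "transform_params"))
  x <- ipds + params$shift
  if (any(x <= 0)) stop("boxcox_transform: ipd + shift must be > 0")
  if (params$lam == 0) log(x) else (x^params$lam - 1) / params$lam
}

#' Inverse Box-Cox transform (transformed scale back to raw seconds)
#'
#' @param y transformed values; must satisfy `lam * y + 1 > 0` for
#'   `lam != 0`
#' @param params a [transform_params()]
#' @return raw-scale values
#' @export
boxcox_inverse <- function(y, params) {
  stopifnot(inherits(params, "transform_params"))
  x <- if (params$lam == 0) exp(y) else {
    base <- params$lam * y + 1
    if (any(base <= 0)) stop("boxcox_inverse: lam * y + 1 must be > 0")
    base^(1 / params$lam)
  }
  x - params$shift
}

#' Apply the Box-Cox transform to a whole IPD table
#' @param table a raw-scale [ipd_table()]
#' @param params a [transform_params()]
#' @return an `ipd_table` on the transformed scale
#' @export
transform_ipd_table <- function(table, params) {
  stopifnot(inherits(table, "ipd_table"))
  if (.ipd_scale(table) != "raw")
    stop("transform_ipd_table expects a raw-scale table")
  out <- table
  out$ipd <- boxcox_transform(table$ipd, params)
  attr(out, "scale") <- "transformed"
  out
}

# bias-uncorrected sample moments (the diagnostic convention: a normal
# sample has skewness 0 and kurtosis 3)
.skewness <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  mean((x - m)^3) / s2^1.5
}
.kurtosis <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  mean((x - m)^4) / s2^2
}

#' Calibrate the Box-Cox parameters from per-position raw IPD vectors
#'
#' Chooses `(lam, shift)` so that the distribution of per-position sample
#' skewness of the transformed IPDs is centered at zero, measured by the
#' median across positions (robust to heavy-tailed positions). For each
#' candidate shift, `lam` is found by a grid pass over
#' `{0, 0.05, ..., 1}` followed by golden-section refinement. The skewness
#' objective alone does not identify the pair — a whole ridge of
#' `(lam, shift)` combinations zeroes the median skewness — so among shifts
#' whose refined objective is within `tie_tol` of the best, the one whose
#' median per-position kurtosis is closest to the normal value 3 is taken
#' (the transform's purpose is normality, of which skewness is only the
#' primary symptom).
#'
#' @param per_position_ipds list of numeric vectors of raw IPDs, one per
#'   genomic position; at least 50 positions with coverage >= 10 are required
#' @param lam_grid,shift_grid search grids
#' @param tie_tol skewness-objective band within which the kurtosis
#'   tie-break applies
#' @return a [transform_params()] with the achieved median skewness recorded
#' @export
calibrate_transform <- function(per_position_ipds,
                                lam_grid = seq(0, 1, by = 0.05),
                                shift_grid = c(0, 0.01, 0.05, 0.1),
                                tie_tol = 0.02) {
  keep <- vapply(per_position_ipds, length, 1L) >= 10L
  pp <- per_position_ipds[keep]
  if (length(pp) < 50L)
    stop("calibrate_transform: need >= 50 positions with coverage >= 10")
  if (all(vapply(pp, function(x) max(x) == min(x), TRUE)))
    stop("calibrate_transform: all positions constant; skewness undefined")
  med_stat <- function(lam, shift, stat) {
    p <- transform_params(lam, shift)
    median(vapply(pp, function(x) stat(boxcox_transform(x, p)), 1.0),
           na.rm = TRUE)
  }
  cand <- lapply(shift_grid, function(s) {
    obj <- vapply(lam_grid, function(l) abs(med_stat(l, s, .skewness)), 1.0)
    i <- which.min(obj)
    step <- if (length(lam_grid) > 1L) min(diff(sort(lam_grid))) else 0.05
    opt <- optimize(function(l) abs(med_stat(l, s, .skewness)),
                    lower = max(min(lam_grid), lam_grid[i] - step),
                    upper = min(max(lam_grid), lam_grid[i] + step),
                    tol = 1e-4)
    lam <- if (opt$objective <= obj[i]) opt$minimum else lam_grid[i]
    list(lam = lam, shift = s,
         obj = abs(med_stat(lam, s, .skewness)),
         kurt = med_stat(lam, s, .kurtosis))
  })
  objs <- vapply(cand, `[[`, 1.0, "obj")
  near <- which(objs <= min(objs) + tie_tol)
  pick <- near[which.min(abs(vapply(cand[near], `[[`, 1.0, "kurt") - 3))]
  best <- cand[[pick]]
  transform_params(best$lam, best$shift,
                   median_skewness = med_stat(best$lam, best$shift,
                                              .skewness))
}

#' Per-position skewness and kurtosis of transformed IPDs
#'
#' Diagnostic used to judge the transform: with a well-chosen transform the
#' per-position skewness distribution is approximately centered at 0 and the
#' kurtosis distribution at 3. Computed with bias-uncorrected sample moments
#' on all positions at or above `min_cov` coverage.
#'
#' @param table a raw-scale [ipd_table()]
#' @param params a [transform_params()]
#' @param min_cov minimum per-position coverage (>= 5)
#' @return data frame with `ref_name`, `position`, `strand`, `coverage`,
#'   `skewness`, `kurtosis`
#' @export
skewness_kurtosis_profile <- function(table, params, min_cov = 5L) {
  stopifnot(min_cov >= 5L)
  y <- boxcox_transform(table$ipd, params)
  key <- paste(table$ref_name, table$position, table$strand, sep = "\r")
  groups <- split(y, key)
  groups <- groups[lengths(groups) >= min_cov]
  if (!length(groups))
    return(data.frame(ref_name = character(), position = integer(),
                      strand = character(), coverage = integer(),
                      skewness = numeric(), kurtosis = numeric()))
  parts <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  data.frame(
    ref_name = parts[, 1L],
    position = as.integer(parts[, 2L]),
    strand = parts[, 3L],
    coverage = lengths(groups),
    skewness = vapply(groups, .skewness, 1.0),
    kurtosis = vapply(groups, .kurtosis, 1.0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove per-movie batch effects by centering
#'
#' Each movie (data-acquisition session) imposes a roughly additive shift on
#' the transformed IPD scale. Centering subtracts from every observation the
#' mean transformed IPD over all alignable observations in its movie, so
#' per-movie means of the output are exactly zero. Idempotent.
#'
#' @param table a transformed-scale [ipd_table()] (a centered table passes
#'   through with zero offsets)
#' @return list with `table` (centered `ipd_table`) and `offsets` (named
#'   numeric vector of per-movie means removed)
#' @export
normalize_movies <- function(table) {
  stopifnot(inherits(table, "ipd_table"))
  if (.ipd_scale(table) == "raw")
    stop("normalize_movies expects a transformed table")
  if (!nrow(table)) {
    out <- table; attr(out, "scale") <- "centered"
    return(list(table = out, offsets = setNames(numeric(), character())))
  }
  mv <- table$movie_id
  offsets <- vapply(split(table$ipd, mv), mean, 1.0)
  singletons <- names(which(table(mv) == 1L))
  if (length(singletons))
    warning("movie(s) with a single observation centered to exactly 0: ",
            paste(singletons, collapse = ", "))
  out <- table
  out$ipd <- table$ipd - offsets[mv]
  attr(out, "scale") <- "centered"
  list(table = out, offsets = offsets)
}

#' Position-specific kinetic rates
#'
#' The estimated kinetic rate of a position is the mean of its (transformed,
#' centered) IPDs; one rate per (reference, position, strand) with coverage
#' at or above `min_cov`.
#'
#' @param table a transformed or centered [ipd_table()]
#' @param min_cov minimum coverage (>= 1)
#' @return data frame with `ref_name`, `position`, `strand`, `rate`,
#'   `coverage`
#' @export
position_rates <- function(table, min_cov = 1L) {
  stopifnot(min_cov >= 1L)
  key <- paste(table$ref_name, table$position, table$strand, sep = "\r")
  groups <- split(table$ipd, key)
  groups <- groups[lengths(groups) >= min_cov]
  if (!length(groups))
    return(data.frame(ref_name = character(), position = integer(),
                      strand = character(), rate = numeric(),
                      coverage = integer()))
  parts <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  out <- data.frame(
    ref_name = parts[, 1L],
    position = as.integer(parts[, 2L]),
    strand = parts[, 3L],
    rate = vapply(groups, mean, 1.0),
    coverage = lengths(groups),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$ref_name, out$position, out$strand), , drop = FALSE]
}

#' Robust outlier removal on the transformed scale
#'
#' Drops values outside `median +/- k * MAD` (scaled median absolute
#' deviation, consistent for the SD under normality). Vectors shorter than 4
#' are returned unchanged. A zero MAD means at least half the values equal
#' the median: an all-equal vector passes through untouched, otherwise the
#' deviating minority is treated as outlying (no finite robust scale
#' exists).
#'
#' @param ipds numeric vector of transformed IPDs
#' @param k positive multiplier; default 4
#' @return filtered vector
#' @export
remove_outliers <- function(ipds, k = 4) {
  stopifnot(k > 0)
  if (length(ipds) < 4L) return(ipds)
  med <- median(ipds)
  s <- mad(ipds)   # scaled MAD, constant 1.4826
  if (s == 0) {
    if (all(ipds == med)) return(ipds)
    return(ipds[ipds == med])
  }
  ipds[abs(ipds - med) <= k * s]
}
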