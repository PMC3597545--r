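#' Genome-wide modification scanning
#'
#' Scores every (position, strand) of the native sample with native coverage
#' at or above `min_native_cov`, per strand independently (SMRT reads are
#' strand specific). Hierarchical methods require the position's sequence
#' context to be present in the homolog index; positions with an unindexed
#' or undefined context are skipped and counted in the `n_skipped_context`
#' attribute of the result.
#'
#' Methods: `hier_control` (marginal log-likelihood ratio using control +
#' homologs; positions with no control reads fall back to the
#' without-control special case), `hier_nocontrol` (homologs only) and
#' `case_control` (Welch baseline, needs control reads at the position).
#'
#' @param native centered [ipd_table()] of the native sample
#' @param control optional centered [ipd_table()] of the WGA control
#' @param index a [build_context_index()] result (hierarchical methods)
#' @param genome genome map from [read_reference()]
#' @param window a [context_window()]; defaults to the index's window
#' @param min_native_cov minimum native coverage per position (default 3;
#'   below this the free-mean profile is meaningless)
#' @param method one of `"hier_control"`, `"hier_nocontrol"`,
#'   `"case_control"`
#' @param tol,max_iter EM settings passed to the scorer
#' @return a `score_table` data frame: `ref_name`, `position`, `strand`,
#'   `score`, `method`, `native_cov`, `control_cov`, `n_homologs`, `context`
#' @export
scan_genome <- function(native, control = NULL, index = NULL, genome = NULL,
                        window = NULL, min_native_cov = 3L,
                        method = c("hier_control", "hier_nocontrol",
                                   "case_control"),
                        tol = 1e-8, max_iter = 500L) {
  method <- match.arg(method)
  if (method == "hier_control" && is.null(control))
    stop("scan_genome: method 'hier_control' needs a control table")
  if (method %in% c("hier_control", "hier_nocontrol")) {
    stopifnot(inherits(index, "context_index"), !is.null(genome))
    if (is.null(window)) window <- index$window
  }
  if (.ipd_scale(native) == "raw")
    stop("scan_genome: tables must be transformed and centered")
  nkey <- paste(native$ref_name, native$position, native$strand, sep = "\r")
  ngroups <- split(native$ipd, nkey)
  ngroups <- ngroups[lengths(ngroups) >= min_native_cov]
  empty <- data.frame(ref_name = character(), position = integer(),
                      strand = character(), score = numeric(),
                      method = character(), native_cov = integer(),
                      control_cov = integer(), n_homologs = integer(),
                      context = character(), stringsAsFactors = FALSE)
  if (!length(ngroups)) {
    return(structure(empty, n_skipped_context = 0L,
                     class = c("score_table", "data.frame")))
  }
  parts <- do.call(rbind, strsplit(names(ngroups), "\r", fixed = TRUE))
  ref <- parts[, 1L]; pos <- as.integer(parts[, 2L]); std <- parts[, 3L]
  cgroups <- if (!is.null(control)) {
    if (.ipd_scale(control) == "raw")
      stop("scan_genome: tables must be transformed and centered")
    split(control$ipd,
          paste(control$ref_name, control$position, control$strand,
                sep = "\r"))
  } else NULL
  ctx <- rep(NA_character_, length(ngroups))
  if (method != "case_control") {
    for (rn in unique(ref)) {
      sel <- ref == rn
      ctx[sel] <- extract_context(genome, rn, pos[sel], std[sel], window)
    }
    # per-context homolog sufficient stats, computed once
    hstats_by_ctx <- lapply(index$entries, function(vs)
      do.call(rbind, lapply(vs, .gstats)))
  }
  n_skipped <- 0L
  rows <- vector("list", length(ngroups))
  for (i in seq_along(ngroups)) {
    nvec <- ngroups[[i]]
    cvec <- if (!is.null(cgroups)) cgroups[[names(ngroups)[i]]] else NULL
    if (method == "case_control") {
      if (is.null(cvec) || !length(cvec)) next
      sc <- case_control_score(nvec, cvec)
      nh <- 0L
    } else {
      cx <- ctx[i]
      if (is.na(cx) || is.null(hstats_by_ctx[[cx]])) {
        n_skipped <- n_skipped + 1L
        next
      }
      hstats <- hstats_by_ctx[[cx]]
      nh <- nrow(hstats)
      cns <- if (method == "hier_control" && !is.null(cvec) && length(cvec))
        .gstats(cvec) else NULL
      sc <- .score_stats(.gstats(nvec), cns, hstats,
                         tol = tol, max_iter = max_iter)$score
    }
    rows[[i]] <- data.frame(
      ref_name = ref[i], position = pos[i], strand = std[i],
      score = sc, method = method, native_cov = length(nvec),
      control_cov = if (is.null(cvec)) 0L else length(cvec),
      n_homologs = nh,
      context = if (method == "case_control") NA_character_ else ctx[i],
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$ref_name, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_skipped_context = n_skipped,
            class = c("score_table", "data.frame"))
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d scored position(s)%s\n", nrow(x),
              if (!is.null(attr(x, "n_skipped_context")))
                sprintf(" (%d skipped: context not indexed)",
                        attr(x, "n_skipped_context")) else ""))
  if (nrow(x)) print(head(as.data.frame(x), 6L))
  invisible(x)
}

#' Naive case-control score (Welch baseline)
#'
#' Absolute Welch two-sample t statistic between native and control
#' transformed, centered IPDs; larger means more evidence of modification.
#' If the Welch denominator degenerates (a size-1 group alongside a
#' zero-variance group), a pooled-variance fallback is used and flagged with
#' attribute `pooled_fallback`.
#'
#' @param native,control non-empty numeric vectors
#' @return `|t|` (scalar); 0 when both groups are identical constants
#' @export
case_control_score <- function(native, control) {
  stopifnot(length(native) >= 1L, length(control) >= 1L)
  n1 <- length(native); n2 <- length(control)
  m1 <- mean(native); m2 <- mean(control)
  v1 <- if (n1 > 1L) var(native) else 0
  v2 <- if (n2 > 1L) var(control) else 0
  se2 <- v1 / n1 + v2 / n2
  if (se2 > 0) return(abs(m1 - m2) / sqrt(se2))
  # degenerate: pooled-variance fallback
  sp2 <- (sum((native - m1)^2) + sum((control - m2)^2)) /
    max(n1 + n2 - 2L, 1L)
  if (sp2 == 0) {
    out <- if (m1 == m2) 0 else Inf
  } else out <- abs(m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  structure(out, pooled_fallback = TRUE)
}

#' Threshold scores into modification calls
#'
#' @param scores a score table
#' @param threshold minimum score (finite)
#' @return the subset with `score >= threshold`, stably ordered by
#'   (reference, position, strand)
#' @export
call_modifications <- function(scores, threshold) {
  stopifnot(is.finite(threshold) || is.infinite(threshold))
  out <- scores[!is.na(scores$score) & scores$score >= threshold, ,
                drop = FALSE]
  out <- out[order(out$ref_name, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
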