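#' Match detections against known modified sites
#'
#' A call is a true positive iff a truth site on the same reference (and, by
#' default, the same strand) lies within `tol_bp` of it — an inclusive
#' boundary, so a call exactly `tol_bp` away still matches. Each truth site
#' counts at most once toward the matched-truth total, regardless of how
#' many calls fall near it. TPR divides matched truth sites by the number of
#' truth sites; FDR divides false calls by the number of calls.
#'
#' @param calls data frame with `ref_name`, `position`, `strand`
#' @param truth a [truth_set()]
#' @param tol_bp non-negative positional tolerance (default 5)
#' @param same_strand require matching strand (default `TRUE`; detection is
#'   strand-specific throughout)
#' @return list with `tp`, `fp`, `matched_truth`, `n_truth`, `fdr`, `tpr`
#' @export
match_detections <- function(calls, truth, tol_bp = 5L, same_strand = TRUE) {
  stopifnot(tol_bp >= 0L)
  n_calls <- nrow(calls)
  n_truth <- nrow(truth)
  if (n_calls == 0L)
    return(list(tp = 0L, fp = 0L, matched_truth = 0L, n_truth = n_truth,
                fdr = NA_real_,
                tpr = if (n_truth) 0 else NA_real_))
  ckey <- if (same_strand) paste(calls$ref_name, calls$strand) else calls$ref_name
  tkey <- if (same_strand) paste(truth$ref_name, truth$strand) else truth$ref_name
  tp <- logical(n_calls)
  matched <- logical(n_truth)
  for (k in unique(ckey)) {
    ci <- which(ckey == k); ti <- which(tkey == k)
    if (!length(ti)) next
    d <- abs(outer(calls$position[ci], truth$position[ti], "-"))
    hit <- d <= tol_bp
    tp[ci] <- rowSums(hit) > 0L
    matched[ti] <- matched[ti] | colSums(hit) > 0L
  }
  tpc <- sum(tp); fpc <- n_calls - tpc
  list(tp = tpc, fp = fpc, matched_truth = sum(matched), n_truth = n_truth,
       fdr = fpc / n_calls,
       tpr = if (n_truth) sum(matched) / n_truth else NA_real_)
}

#' FDR/TPR curve over all score thresholds
#'
#' Sweeps the thresholds given by the unique scores (descending) and reports
#' the operating point of each.
#'
#' @param scores a score table
#' @param truth a [truth_set()]
#' @param tol_bp positional matching tolerance
#' @param same_strand require matching strand
#' @return data frame with `threshold`, `tp`, `fp`, `tpr`, `fdr`
#' @export
roc_curve <- function(scores, truth, tol_bp = 5L, same_strand = TRUE) {
  thr <- sort(unique(scores$score[is.finite(scores$score)]),
              decreasing = TRUE)
  rows <- lapply(thr, function(t) {
    m <- match_detections(call_modifications(scores, t), truth,
                          tol_bp = tol_bp, same_strand = same_strand)
    data.frame(threshold = t, tp = m$tp, fp = m$fp, tpr = m$tpr,
               fdr = m$fdr)
  })
  do.call(rbind, rows)
}

#' Rank-based ROC AUC of scores against positional truth
#'
#' Positions are labelled positive when they coincide with a truth site
#' (same strand; `tol_bp = 0`), or lie within `tol_bp` of one; the AUC is
#' the Mann-Whitney probability that a random positive outscores a random
#' negative. The default labels only the modified bases themselves, so
#' flanking positions elevated by a modification footprint count against
#' the score, making the AUC conservative.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`
#' @export
score_auc <- function(scores, truth, tol_bp = 0L, same_strand = TRUE) {
  lab <- logical(nrow(scores))
  ckey <- if (same_strand) paste(scores$ref_name, scores$strand) else scores$ref_name
  tkey <- if (same_strand) paste(truth$ref_name, truth$strand) else truth$ref_name
  for (k in unique(ckey)) {
    ti <- which(tkey == k)
    if (!length(ti)) next
    ci <- which(ckey == k)
    d <- abs(outer(scores$position[ci], truth$position[ti], "-"))
    lab[ci] <- rowSums(d <= tol_bp) > 0L
  }
  s <- scores$score
  npos <- sum(lab); nneg <- sum(!lab)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(s)
  (sum(r[lab]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# subsample each position's observations without replacement to `target`
.subsample_table <- function(table, target) {
  key <- paste(table$ref_name, table$position, table$strand, sep = "\r")
  idx <- unlist(lapply(split(seq_len(nrow(table)), key), function(ii) {
    if (length(ii) < target) {
      p <- strsplit(names(which.max(table(key[ii]))), "\r")[[1L]]
      stop(sprintf(
        "subsampling target %d exceeds coverage %d at %s:%s (%s)",
        target, length(ii), table$ref_name[ii[1L]],
        table$position[ii[1L]], table$strand[ii[1L]]))
    }
    sample(ii, target)
  }), use.names = FALSE)
  out <- table[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average FDR at fixed TPR levels under read subsampling
#'
#' For each coverage target, per-position observations of the native and
#' control tables are subsampled without replacement `n_rep` times; each
#' replicate is scored by `scorer` and its threshold sweep is reduced to the
#' FDR attained when the TPR first reaches each level of `tpr_grid`. The
#' reported curve is the FDR averaged across replicates.
#'
#' @param native,control centered [ipd_table()]s (control may be `NULL` for
#'   scorers that ignore it)
#' @param truth a [truth_set()]
#' @param coverage_targets list of `c(native = , control = )` integer pairs;
#'   `NA` leaves a table unsubsampled
#' @param n_rep number of subsampling replicates (default 100)
#' @param scorer `function(native_table, control_table)` returning a score
#'   table
#' @param tpr_grid TPR levels at which FDR is read off
#' @param tol_bp positional matching tolerance
#' @return data frame with `native_cov`, `control_cov`, `tpr`, `fdr`
#'   (replicate mean), `fdr_se`
#' @export
roc_by_subsampling <- function(native, control, truth, coverage_targets,
                               n_rep = 100L, scorer,
                               tpr_grid = seq(0.1, 1, by = 0.1),
                               tol_bp = 5L) {
  fdr_at_tpr <- function(curve) {
    vapply(tpr_grid, function(t) {
      ok <- which(curve$tpr >= t)
      if (!length(ok)) NA_real_ else curve$fdr[ok[1L]]
    }, 1.0)
  }
  out <- list()
  for (tgt in coverage_targets) {
    reps <- matrix(NA_real_, n_rep, length(tpr_grid))
    for (r in seq_len(n_rep)) {
      nat <- if (is.na(tgt[["native"]])) native else
        .subsample_table(native, tgt[["native"]])
      ctl <- if (is.null(control) || is.na(tgt[["control"]])) control else
        .subsample_table(control, tgt[["control"]])
      curve <- roc_curve(scorer(nat, ctl), truth, tol_bp = tol_bp)
      reps[r, ] <- fdr_at_tpr(curve)
    }
    out[[length(out) + 1L]] <- data.frame(
      native_cov = tgt[["native"]], control_cov = tgt[["control"]],
      tpr = tpr_grid,
      fdr = colMeans(reps, na.rm = TRUE),
      fdr_se = apply(reps, 2L, function(v)
        sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v)))))
  }
  do.call(rbind, out)
}

#' Locate motif occurrences and the scored base within them
#'
#' Finds occurrences of `motif` on both strands of every reference and
#' returns the genomic position and strand of the base at `motif_offset`
#' (0-based within the motif, read 5'->3' on the matching strand).
#'
#' @param genome genome map
#' @param motif character motif over ACGT
#' @param motif_offset 0-based index of the scored base within the motif
#' @return data frame with `ref_name`, `position`, `strand`
#' @export
motif_sites <- function(genome, motif, motif_offset) {
  stopifnot(!grepl("[^ACGT]", motif), motif_offset >= 0,
            motif_offset < nchar(motif))
  L <- nchar(motif)
  rows <- list()
  for (rn in names(genome)) {
    subj <- Biostrings::DNAString(genome[[rn]])
    fwd <- Biostrings::start(
      Biostrings::matchPattern(Biostrings::DNAString(motif), subj))
    if (length(fwd))
      rows[[length(rows) + 1L]] <- data.frame(
        ref_name = rn, position = fwd - 1L + motif_offset, strand = "+",
        stringsAsFactors = FALSE)
    rev <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(motif)), subj))
    if (length(rev))
      rows[[length(rows) + 1L]] <- data.frame(
        ref_name = rn, position = rev - 1L + (L - 1L - motif_offset),
        strand = "-", stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(ref_name = character(), position = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  unique(do.call(rbind, rows))
}

#' Conservative motif-based FDR
#'
#' In a genome where a motif (for example GATC, whose adenines are almost
#' universally methylated in wild-type E. coli K-12) is expected to carry
#' nearly all true modifications of a given base, the ratio of significant
#' calls at that base letter *outside* the motif context to all significant
#' calls at that base letter is a conservative FDR estimate (off-motif true
#' modifications inflate it).
#'
#' @param scores a score table
#' @param genome genome map
#' @param motif motif over ACGT
#' @param motif_offset 0-based index of the modified base within the motif
#' @param threshold significance threshold on the score
#' @return the conservative FDR, or `NA` (with a warning) if the motif does
#'   not occur in the genome or no significant call hits the base letter
#' @export
motif_fdr <- function(scores, genome, motif, motif_offset, threshold) {
  sites <- motif_sites(genome, motif, motif_offset)
  if (!nrow(sites)) {
    warning("motif ", motif, " not found in genome")
    return(NA_real_)
  }
  base <- substr(motif, motif_offset + 1L, motif_offset + 1L)
  sig <- call_modifications(scores, threshold)
  if (!nrow(sig)) return(NA_real_)
  # the base letter a call interrogates, read on its own strand
  called_base <- mapply(function(rn, p, s) {
    b <- substr(genome[[rn]], p + 1L, p + 1L)
    if (s == "-") chartr("ACGT", "TGCA", b) else b
  }, sig$ref_name, sig$position, sig$strand)
  sig <- sig[called_base == base, , drop = FALSE]
  if (!nrow(sig)) {
    warning("no significant call at base ", base)
    return(NA_real_)
  }
  in_motif <- paste(sig$ref_name, sig$position, sig$strand) %in%
    paste(sites$ref_name, sites$position, sites$strand)
  sum(!in_motif) / nrow(sig)
}

#' Restrict scores to neighbourhoods of anchor positions
#'
#' Keeps score records within `radius_bp` (inclusive) of any anchor on the
#' same reference, either strand — the region convention used when
#' evaluating detection around known motif sites.
#'
#' @param scores a score table
#' @param anchor_positions data frame with `ref_name`, `position`
#' @param radius_bp non-negative radius (default 20)
#' @return the subset of `scores`
#' @export
restrict_to_neighborhoods <- function(scores, anchor_positions,
                                      radius_bp = 20L) {
  stopifnot(radius_bp >= 0L)
  if (!nrow(anchor_positions) || !nrow(scores))
    return(scores[integer(), , drop = FALSE])
  keep <- logical(nrow(scores))
  for (rn in unique(scores$ref_name)) {
    ai <- anchor_positions$position[anchor_positions$ref_name == rn]
    if (!length(ai)) next
    si <- which(scores$ref_name == rn)
    d <- abs(outer(scores$position[si], ai, "-"))
    keep[si] <- rowSums(d <= radius_bp) > 0L
  }
  out <- scores[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Empirical FDR from a modification-free sample
#'
#' Detections called in a WGA sample (where nothing should be modified)
#' divided by detections called in the native sample at the same threshold.
#'
#' @param native_scores,wga_scores score tables
#' @param threshold score threshold applied to both
#' @return the ratio, `NA` if the native sample yields no calls
#' @export
empirical_fdr <- function(native_scores, wga_scores, threshold) {
  n_nat <- nrow(call_modifications(native_scores, threshold))
  if (n_nat == 0L) return(NA_real_)
  nrow(call_modifications(wga_scores, threshold)) / n_nat
}
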