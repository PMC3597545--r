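#' Sequence-context window
#'
#' A local window around the incorporation site, expressed on the sequenced
#' strand: `upstream` bases 5' of the site and `downstream` bases 3' of it,
#' for a total context length of `upstream + downstream + 1`. The default
#' `(6, 1)` (an 8-base context) maximises context sharing across datasets;
#' `(7, 2)` is the window at which context dependence of the kinetics
#' saturates.
#'
#' @param upstream non-negative integer
#' @param downstream non-negative integer
#' @return a `context_window`
#' @export
context_window <- function(upstream = 6L, downstream = 1L) {
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  stopifnot(upstream >= 0L, downstream >= 0L)
  structure(list(upstream = upstream, downstream = downstream,
                 length = upstream + downstream + 1L),
            class = "context_window")
}

#' @export
print.context_window <- function(x, ...) {
  cat(sprintf("<context_window> [-%d,+%d] (length %d)\n",
              x$upstream, x$downstream, x$length))
  invisible(x)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract local sequence contexts
#'
#' For a `+`-strand position the context is the forward-strand substring
#' covering `[position - upstream, position + downstream]`, read 5'->3'. For
#' a `-`-strand position it is the reverse complement of the forward-strand
#' substring `[position - downstream, position + upstream]`, so that
#' "upstream" again precedes the incorporation site 5'->3' on the sequenced
#' strand. Windows that overrun a contig end or contain a non-ACGT symbol
#' yield `NA` (contexts carry no kinetic meaning there), which is distinct
#' from the error raised for an unknown reference name.
#'
#' Vectorised over `position` and `strand`.
#'
#' @param genome named character vector from [read_reference()]
#' @param ref_name reference name (scalar)
#' @param position 0-based integer position(s)
#' @param strand `"+"` or `"-"`, recycled
#' @param window a [context_window()]
#' @return character vector of contexts, `NA` where undefined
#' @export
extract_context <- function(genome, ref_name, position, strand, window) {
  stopifnot(inherits(window, "context_window"))
  if (!ref_name %in% names(genome)) stop("unknown reference: ", ref_name)
  seq <- genome[[ref_name]]
  len <- nchar(seq)
  n <- max(length(position), length(strand))
  position <- rep_len(as.integer(position), n)
  strand <- rep_len(strand, n)
  minus <- strand == "-"
  # 0-based inclusive window on the forward strand
  lo <- ifelse(minus, position - window$downstream, position - window$upstream)
  hi <- ifelse(minus, position + window$upstream, position + window$downstream)
  ok <- lo >= 0L & hi <= len - 1L
  ctx <- rep(NA_character_, n)
  if (any(ok))
    ctx[ok] <- substring(seq, lo[ok] + 1L, hi[ok] + 1L)
  valid <- !is.na(ctx) & !grepl("[^ACGT]", ctx)
  ctx[!valid] <- NA_character_
  flip <- valid & minus
  if (any(flip)) ctx[flip] <- .revcomp(ctx[flip])
  ctx
}

#' Build an index of homologous positions from historical data
#'
#' Homologous positions are genomic positions (in any dataset, either strand)
#' sharing the same local sequence context; their per-position transformed
#' IPD vectors form the pooling unit of the hierarchical model. A context is
#' retained only when at least `min_positions` positions reach coverage
#' `min_cov`; per-position vectors are stored intact, never pooled, because
#' the model needs the between-position heterogeneity.
#'
#' @param tables a centered [ipd_table()] or list of them (historical /
#'   control WGA datasets of the same chemistry)
#' @param genomes a genome map from [read_reference()], or a list parallel to
#'   `tables`
#' @param window a [context_window()]
#' @param min_cov minimum per-position coverage (default 10; applied as
#'   `coverage >= min_cov`)
#' @param min_positions minimum number of qualifying positions per context
#'   (default 6, i.e. strictly more than 5)
#' @return a `context_index`
#' @export
build_context_index <- function(tables, genomes, window = context_window(),
                                min_cov = 10L, min_positions = 6L) {
  stopifnot(inherits(window, "context_window"))
  if (inherits(tables, "ipd_table")) tables <- list(tables)
  if (!is.list(genomes) || is.character(genomes)) genomes <- list(genomes)
  genomes <- rep_len(genomes, max(1L, length(tables)))
  entries <- list(); meta <- list(); n_skipped <- 0L
  for (t in seq_along(tables)) {
    tab <- tables[[t]]
    if (!nrow(tab)) next
    if (.ipd_scale(tab) == "raw")
      stop("build_context_index expects transformed/centered tables")
    genome <- genomes[[t]]
    key <- paste(tab$ref_name, tab$position, tab$strand, sep = "\r")
    groups <- split(tab$ipd, key)
    groups <- groups[lengths(groups) >= min_cov]
    if (!length(groups)) next
    parts <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
    ctx <- unlist(lapply(unique(parts[, 1L]), function(rn) {
      sel <- parts[, 1L] == rn
      out <- rep(NA_character_, sum(sel))
      out <- extract_context(genome, rn, as.integer(parts[sel, 2L]),
                             parts[sel, 3L], window)
      names(out) <- which(sel)
      out
    }))
    ctx <- ctx[order(as.integer(names(ctx)))]
    n_skipped <- n_skipped + sum(is.na(ctx))
    for (i in which(!is.na(ctx))) {
      cx <- ctx[[i]]
      entries[[cx]] <- c(entries[[cx]], groups[i])
      meta[[cx]] <- rbind(meta[[cx]], data.frame(
        source = t, ref_name = parts[i, 1L],
        position = as.integer(parts[i, 2L]), strand = parts[i, 3L],
        coverage = length(groups[[i]]), stringsAsFactors = FALSE))
    }
  }
  keep <- names(entries)[vapply(entries, length, 1L) >= min_positions]
  structure(list(window = window,
                 entries = entries[keep], meta = meta[keep],
                 min_cov = min_cov, min_positions = min_positions,
                 n_skipped_contexts = n_skipped),
            class = "context_index")
}

#' @export
print.context_index <- function(x, ...) {
  np <- sum(vapply(x$entries, length, 1L))
  cat(sprintf("<context_index> [-%d,+%d]: %d contexts, %d positions (min_cov=%d, min_positions=%d)\n",
              x$window$upstream, x$window$downstream,
              length(x$entries), np, x$min_cov, x$min_positions))
  invisible(x)
}

#' Per-context mean kinetic rates (context effects)
#'
#' The context effect of a sequence context is the grand mean transformed IPD
#' over all observations at all member positions of the context.
#'
#' @param index a [build_context_index()] result
#' @return data frame with `context`, `effect`, `n_positions`, `n_obs`
#' @export
context_effect <- function(index) {
  stopifnot(inherits(index, "context_index"))
  if (!length(index$entries)) stop("context_effect: empty index")
  ctx <- sort(names(index$entries))
  data.frame(
    context = ctx,
    effect = vapply(index$entries[ctx],
                    function(vs) mean(unlist(vs, use.names = FALSE)), 1.0),
    n_positions = vapply(index$entries[ctx], length, 1L),
    n_obs = vapply(index$entries[ctx],
                   function(vs) sum(lengths(vs)), 1L),
    row.names = NULL, stringsAsFactors = FALSE)
}

# one-hot encoding: 4 indicators per window slot
.onehot_contexts <- function(contexts) {
  L <- nchar(contexts[1L])
  bases <- c("A", "C", "G", "T")
  m <- matrix(0, length(contexts), 4L * L)
  colnames(m) <- paste0("s", rep(seq_len(L), each = 4L), "_",
                        rep(bases, L))
  chars <- do.call(rbind, strsplit(contexts, "", fixed = TRUE))
  for (j in seq_len(L)) for (b in seq_along(bases))
    m[, (j - 1L) * 4L + b] <- as.numeric(chars[, j] == bases[b])
  m
}

#' Regress position-specific kinetic rates on sequence context
#'
#' Fits gradient-boosted regression trees (any member of the MART family)
#' with one-hot context features, one block of 4 indicators per window slot;
#' interactions between slots are left to the trees. Performance is the mean
#' over 5 cross-validation folds of `1 - SS_res/SS_tot` on the held-out 20%.
#'
#' @param rates numeric response vector (position-specific kinetic rates)
#' @param contexts parallel character vector of contexts, one per rate, all
#'   the same length
#' @param nrounds,max_depth,learning_rate boosting hyperparameters
#' @param nfold number of CV folds
#' @param fold_seed seed for the fold assignment (recorded in the result)
#' @return list of class `context_fit` with `model`, `cv_r2`, `fold_r2`,
#'   `fold_seed`
#' @export
fit_context_regression <- function(rates, contexts, nrounds = 500L,
                                   max_depth = 4L, learning_rate = 0.05,
                                   nfold = 5L, fold_seed = 1L) {
  stopifnot(length(rates) == length(contexts))
  if (length(rates) < 500L)
    stop("fit_context_regression: need >= 500 (rate, context) pairs")
  X <- .onehot_contexts(contexts)
  y <- as.numeric(rates)
  params <- xgboost::xgb.params(objective = "reg:squarederror",
                                max_depth = max_depth,
                                learning_rate = learning_rate, nthread = 1L)
  if (var(y) == 0) {
    model <- xgboost::xgb.train(params, xgboost::xgb.DMatrix(X, label = y),
                                nrounds = 1L, verbose = 0L)
    fit <- list(model = model, cv_r2 = 0, fold_r2 = rep(0, nfold),
                fold_seed = fold_seed, window_length = nchar(contexts[1L]))
    class(fit) <- "context_fit"
    return(fit)
  }
  folds <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(fold_seed)
    sample(rep_len(seq_len(nfold), length(y)))
  })
  fold_r2 <- vapply(seq_len(nfold), function(k) {
    tr <- folds != k
    m <- xgboost::xgb.train(params,
                            xgboost::xgb.DMatrix(X[tr, , drop = FALSE],
                                                 label = y[tr]),
                            nrounds = nrounds, verbose = 0L)
    pred <- predict(m, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
    yt <- y[!tr]
    1 - sum((yt - pred)^2) / sum((yt - mean(yt))^2)
  }, 1.0)
  model <- xgboost::xgb.train(params, xgboost::xgb.DMatrix(X, label = y),
                              nrounds = nrounds, verbose = 0L)
  structure(list(model = model, cv_r2 = mean(fold_r2), fold_r2 = fold_r2,
                 fold_seed = fold_seed,
                 window_length = nchar(contexts[1L])),
            class = "context_fit")
}

#' @export
print.context_fit <- function(x, ...) {
  cat(sprintf("<context_fit> boosted trees on %d-base contexts; CV R^2 = %.3f (folds: %s)\n",
              x$window_length, x$cv_r2,
              paste(sprintf("%.3f", x$fold_r2), collapse = ", ")))
  invisible(x)
}

#' @export
predict.context_fit <- function(object, contexts, ...) {
  predict(object$model, xgboost::xgb.DMatrix(.onehot_contexts(contexts)))
}

#' Scan context-window sizes for explanatory power
#'
#' Fits one context regression per (upstream, downstream) grid cell and
#' reports the CV R-squared matrix; saturation of the R-squared as the window
#' grows identifies the informative context extent.
#'
#' @param rates data frame from [position_rates()]
#' @param genome genome map covering the rate positions
#' @param upstream_grid,downstream_grid integer grids (small; at most 10 x 5)
#' @param ... passed to [fit_context_regression()]
#' @return numeric matrix of CV R^2, rows = upstream, cols = downstream
#' @export
window_scan <- function(rates, genome, upstream_grid, downstream_grid, ...) {
  stopifnot(length(upstream_grid) <= 10L, length(downstream_grid) <= 5L)
  out <- matrix(NA_real_, length(upstream_grid), length(downstream_grid),
                dimnames = list(paste0("u", upstream_grid),
                                paste0("d", downstream_grid)))
  for (i in seq_along(upstream_grid)) for (j in seq_along(downstream_grid)) {
    w <- context_window(upstream_grid[i], downstream_grid[j])
    ctx <- rep(NA_character_, nrow(rates))
    for (rn in unique(rates$ref_name)) {
      sel <- rates$ref_name == rn
      ctx[sel] <- extract_context(genome, rn, rates$position[sel],
                                  rates$strand[sel], w)
    }
    ok <- !is.na(ctx)
    out[i, j] <- fit_context_regression(rates$rate[ok], ctx[ok], ...)$cv_r2
  }
  out
}
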