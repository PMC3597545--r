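#' Hyperparameters of the conjugate normal-inverse-chi-square prior
#'
#' Per-position transformed IPDs are modelled as normal with a
#' position-specific mean and variance; across homologous positions these
#' (mean, variance) pairs are iid from the conjugate prior
#' `sigma^2 ~ Scaled-Inv-Chi^2(nu0, tau20)`,
#' `mu | sigma^2 ~ Normal(mu0, sigma^2 / kappa0)`.
#'
#' @param mu0 prior mean of position means (transformed-IPD units)
#' @param kappa0 prior precision multiplier, > 0 (dimensionless)
#' @param nu0 prior degrees of freedom, > 0
#' @param tau20 prior scale, > 0 (squared transformed-IPD units)
#' @return a `nix_hyper` object
#' @export
nix_hyperparams <- function(mu0, kappa0, nu0, tau20) {
  if (!is.finite(mu0) || !is.finite(kappa0) || !is.finite(nu0) ||
      !is.finite(tau20) || kappa0 <= 0 || nu0 <= 0 || tau20 <= 0)
    stop("nix_hyperparams: need finite mu0 and kappa0, nu0, tau20 > 0")
  structure(list(mu0 = mu0, kappa0 = kappa0, nu0 = nu0, tau20 = tau20),
            class = "nix_hyper")
}

#' @export
print.nix_hyper <- function(x, ...) {
  cat(sprintf("<nix_hyper> mu0=%.4g kappa0=%.4g nu0=%.4g tau20=%.4g\n",
              x$mu0, x$kappa0, x$nu0, x$tau20))
  invisible(x)
}

# sufficient statistics (n, mean, centered sum of squares) of one group;
# a variance floor keeps degenerate (constant) groups finite under EM
.gstats <- function(x, ss_floor = 1e-10) {
  n <- length(x); xb <- mean(x)
  c(n = n, mean = xb, ss = max(sum((x - xb)^2), ss_floor))
}

# closed-form log marginal likelihood of groups under the NIX prior,
# vectorised over groups given as (n, mean, ss) columns:
#   p(x) = pi^(-n/2) sqrt(k0/kn) Gamma(nun/2)/Gamma(nu0/2)
#          (nu0 tau20)^(nu0/2) / Sn^(nun/2)
# with kn = k0+n, nun = nu0+n and posterior sum of squares
#   Sn = nu0 tau20 + ss + (k0 n / kn) (xbar - mu0)^2
.ml_groups <- function(n, xbar, ss, h) {
  kn <- h$kappa0 + n
  nun <- h$nu0 + n
  Sn <- h$nu0 * h$tau20 + ss + (h$kappa0 * n / kn) * (xbar - h$mu0)^2
  -n / 2 * log(pi) + 0.5 * (log(h$kappa0) - log(kn)) +
    lgamma(nun / 2) - lgamma(h$nu0 / 2) +
    (h$nu0 / 2) * log(h$nu0 * h$tau20) - (nun / 2) * log(Sn)
}

# log marginal likelihood of a group whose mean is a fixed hyperparameter mu
# and whose variance carries the Scaled-Inv-Chi^2(nu0, tau20) prior
.ml_free <- function(n, xbar, ss, mu, h) {
  S <- ss + n * (xbar - mu)^2
  nun <- h$nu0 + n
  -n / 2 * log(2 * pi) + (h$nu0 / 2) * log(h$nu0 * h$tau20 / 2) -
    lgamma(h$nu0 / 2) + lgamma(nun / 2) -
    (nun / 2) * log((S + h$nu0 * h$tau20) / 2)
}

#' Marginal log-likelihood of one group under the NIX prior
#'
#' Closed form of
#' `log \int\int prod_j N(x_j | mu, s2) N(mu | mu0, s2/kappa0)
#'  ScaledInvChi2(s2 | nu0, tau20) dmu ds2`,
#' via the conjugate posterior-update constants.
#'
#' @param x non-empty numeric vector
#' @param hyper a [nix_hyperparams()]
#' @return log marginal likelihood (scalar)
#' @export
marginal_loglik_group <- function(x, hyper) {
  stopifnot(inherits(hyper, "nix_hyper"), length(x) >= 1L)
  g <- .gstats(x, ss_floor = 0)
  .ml_groups(g[["n"]], g[["mean"]], g[["ss"]], hyper)
}

#' Marginal log-likelihood of a group with a free (hyperparameter) mean
#'
#' The native group's mean is not shrunk toward the prior: only its variance
#' carries the Scaled-Inv-Chi^2 prior, and the mean enters as a
#' hyperparameter. For fixed prior parameters the expression is maximised
#' over `mu` at the sample mean of `x` (it depends on `mu` only through the
#' sum of squared deviations).
#'
#' @param x non-empty numeric vector
#' @param mu the fixed mean
#' @param hyper a [nix_hyperparams()]
#' @return log marginal likelihood (scalar)
#' @export
marginal_loglik_free_mean <- function(x, mu, hyper) {
  stopifnot(inherits(hyper, "nix_hyper"), length(x) >= 1L, is.finite(mu))
  g <- .gstats(x, ss_floor = 0)
  .ml_free(g[["n"]], g[["mean"]], g[["ss"]], mu, hyper)
}

# observed marginal loglik of the whole fit at hyperparameters h
.obs_loglik <- function(gs, ns, h) {
  ll <- if (nrow(gs)) sum(.ml_groups(gs[, 1L], gs[, 2L], gs[, 3L], h)) else 0
  if (!is.null(ns)) ll <- ll + .ml_free(ns[1L], ns[2L], ns[3L], ns[2L], h)
  ll
}

# EM on sufficient statistics. gs: matrix with columns (n, mean, ss), one
# row per NIX group; ns: native (n, mean, ss) with free mean, or NULL.
# The iteration itself lives in compiled code (src/em.cpp): genome-wide
# scanning runs two fits per position.
.em_fit <- function(gs, ns = NULL, init = NULL, tol = 1e-8, max_iter = 500L,
                    keep_trace = TRUE) {
  m <- nrow(gs)
  if (m == 0L && is.null(ns)) stop("EM needs at least one group")
  if (is.null(init)) {
    vars <- c(if (m) gs[, 3L] / gs[, 1L], if (!is.null(ns)) ns[3L] / ns[1L])
    init <- nix_hyperparams(
      mu0 = if (m) mean(gs[, 2L]) else ns[2L],
      kappa0 = 1, nu0 = 4,
      tau20 = max(median(vars), 1e-8))
  }
  res <- .em_fit_cpp(gs, if (is.null(ns)) numeric() else as.numeric(ns),
                     c(init$mu0, init$kappa0, init$nu0, init$tau20),
                     tol, as.integer(max_iter), keep_trace)
  structure(list(hyper = nix_hyperparams(res$hyper[1L], res$hyper[2L],
                                         res$hyper[3L], res$hyper[4L]),
                 mu_native_hat = if (!is.null(ns)) ns[[2L]] else NA_real_,
                 loglik = res$loglik, n_iter = res$n_iter,
                 converged = res$converged,
                 loglik_trace = res$trace),
            class = "nix_fit")
}

#' Fit prior hyperparameters by expectation-maximisation
#'
#' Maximises the marginal likelihood of the hierarchical model over the four
#' prior hyperparameters. The E-step computes, per group, the conjugate
#' normal-inverse-chi-square posterior over (mean, variance) and its
#' sufficient expectations; the M-step updates `mu0` and `kappa0` in closed
#' form and `(nu0, tau20)` by profiling `tau20` and a 1-D bisection root
#' solve in `log(nu0)`. If a native group with a free mean is supplied, its
#' mean is profiled at its sample mean and only its variance participates in
#' the prior. The reported marginal log-likelihood is non-decreasing across
#' iterations.
#'
#' @param groups list of non-empty numeric vectors sharing the NIX prior
#' @param native optional numeric vector whose mean is free
#' @param init optional [nix_hyperparams()] starting point; by default
#'   `mu0` = mean of group means, `tau20` = median of group variances,
#'   `kappa0` = 1, `nu0` = 4
#' @param tol relative log-likelihood convergence tolerance
#' @param max_iter iteration cap; non-convergence returns the best iterate
#'   with `converged = FALSE`
#' @return a `nix_fit`: `hyper`, `mu_native_hat`, `loglik`, `n_iter`,
#'   `converged`, `loglik_trace`
#' @export
fit_hyperparams_em <- function(groups, native = NULL, init = NULL,
                               tol = 1e-8, max_iter = 500L) {
  stopifnot(length(groups) + (!is.null(native)) >= 1L)
  if (length(groups) && any(lengths(groups) < 1L))
    stop("fit_hyperparams_em: empty group")
  gs <- if (length(groups))
    do.call(rbind, lapply(groups, .gstats)) else
    matrix(numeric(), 0L, 3L)
  ns <- if (!is.null(native)) .gstats(native) else NULL
  .em_fit(gs, ns, init = init, tol = tol, max_iter = max_iter)
}

#' @export
print.nix_fit <- function(x, ...) {
  cat(sprintf("<nix_fit> loglik=%.4f after %d iteration(s)%s\n",
              x$loglik, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  print(x$hyper)
  if (is.finite(x$mu_native_hat))
    cat(sprintf("  native mean (profiled): %.4g\n", x$mu_native_hat))
  invisible(x)
}

#' @export
logLik.nix_fit <- function(object, ...) {
  structure(object$loglik, df = 4L + is.finite(object$mu_native_hat),
            class = "logLik")
}

#' @export
coef.nix_fit <- function(object, ...) {
  c(mu0 = object$hyper$mu0, kappa0 = object$hyper$kappa0,
    nu0 = object$hyper$nu0, tau20 = object$hyper$tau20)
}

# maximize the (closed-form) marginal loglik: a short EM phase for a good
# basin, then a quasi-Newton polish. EM alone converges sublinearly when the
# data drive kappa0 or nu0 toward the homogeneous boundary; the polish
# maximizes the identical objective to full precision.
.fit_hyper <- function(gs, ns = NULL, tol = 1e-8, max_iter = 500L) {
  em <- .em_fit(gs, ns, tol = tol, max_iter = min(max_iter, 15L),
                keep_trace = FALSE)
  h <- em$hyper
  nsv <- if (is.null(ns)) numeric() else as.numeric(ns)
  par0 <- c(h$mu0, log(h$kappa0), log(h$nu0), log(h$tau20))
  opt <- try(optim(par0, .negll_cpp, .negll_grad_cpp, gs = gs, ns = nsv,
                   method = "L-BFGS-B",
                   lower = c(-Inf, -18, -4, -27),
                   upper = c(Inf, 18, 8, 27),
                   control = list(factr = 1e6, maxit = 200L)),
             silent = TRUE)
  if (!inherits(opt, "try-error") && is.finite(opt$value) &&
      -opt$value >= em$loglik) {
    em$hyper <- nix_hyperparams(opt$par[1L], exp(opt$par[2L]),
                                exp(opt$par[3L]), exp(opt$par[4L]))
    em$loglik <- -opt$value
    em$converged <- TRUE
  }
  em
}

# shared worker on sufficient statistics; used by the scoring API and by
# scan_genome, where stats are precomputed once per position
.score_stats <- function(native_ns, control_ns = NULL, hstats,
                         tol = 1e-8, max_iter = 500L) {
  if (is.null(control_ns)) {
    if (nrow(hstats) < 1L)
      stop("score_without_control: need at least one homologous position")
    alt <- .fit_hyper(hstats, ns = native_ns, tol = tol,
                      max_iter = max_iter)
    null <- .fit_hyper(rbind(hstats, native_ns), ns = NULL,
                       tol = tol, max_iter = max_iter)
  } else {
    alt <- .fit_hyper(rbind(hstats, control_ns), ns = native_ns,
                      tol = tol, max_iter = max_iter)
    # pooled native+control group from the two groups' sufficient stats
    n1 <- native_ns[1L]; n2 <- control_ns[1L]
    nb <- n1 + n2
    mb <- (n1 * native_ns[2L] + n2 * control_ns[2L]) / nb
    ssb <- native_ns[3L] + control_ns[3L] +
      n1 * (native_ns[2L] - mb)^2 + n2 * (control_ns[2L] - mb)^2
    pooled <- c(n = nb, mean = mb, ss = max(ssb, 1e-10))
    null <- .fit_hyper(rbind(hstats, pooled), ns = NULL,
                       tol = tol, max_iter = max_iter)
  }
  list(score = alt$loglik - null$loglik, alt = alt, null = null)
}

#' Score a position with control data
#'
#' Marginal log-likelihood ratio between the alternative model (control and
#' homologous positions share the NIX prior; the native mean is a free
#' hyperparameter with the shared variance prior) and the null model (native
#' and control IPDs pooled into one exchangeable group alongside the
#' homologs). Hyperparameters are re-fitted by EM under each model. An empty
#' control delegates to [score_without_control()], of which this model is a
#' strict generalisation.
#'
#' @param native non-empty numeric vector of centered transformed IPDs
#' @param control numeric vector (may be empty, see above)
#' @param homologs list of numeric vectors from homologous positions
#' @param tol,max_iter EM settings
#' @param details if `TRUE` return the two fits alongside the score
#' @return the score (scalar), or a list if `details = TRUE`
#' @export
score_with_control <- function(native, control, homologs = list(),
                               tol = 1e-8, max_iter = 500L,
                               details = FALSE) {
  if (!length(native)) stop("score_with_control: empty native group")
  if (!length(control))
    return(score_without_control(native, homologs, tol = tol,
                                 max_iter = max_iter, details = details))
  hstats <- if (length(homologs))
    do.call(rbind, lapply(homologs, .gstats)) else matrix(numeric(), 0L, 3L)
  res <- .score_stats(.gstats(native), .gstats(control), hstats,
                      tol = tol, max_iter = max_iter)
  if (details) res else res$score
}

#' Score a position without control data
#'
#' Special case of [score_with_control()] with no control group: the null
#' distribution is estimated from homologous positions alone. Alternative:
#' homologs under the prior, native with free mean and the shared variance
#' prior. Null: the native group joins the homologs under the prior.
#'
#' @inheritParams score_with_control
#' @return the score (scalar), or a list if `details = TRUE`
#' @export
score_without_control <- function(native, homologs, tol = 1e-8,
                                  max_iter = 500L, details = FALSE) {
  if (!length(native)) stop("score_without_control: empty native group")
  if (!length(homologs))
    stop("score_without_control: need at least one homologous position")
  hstats <- do.call(rbind, lapply(homologs, .gstats))
  res <- .score_stats(.gstats(native), NULL, hstats,
                      tol = tol, max_iter = max_iter)
  if (details) res else res$score
}
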