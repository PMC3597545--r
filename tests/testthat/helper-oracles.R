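# Independent numerical oracles and shared fixtures for the test suite.

# Nested adaptive quadrature of the normal-inverse-chi-square group marginal
# likelihood. The conjugate posterior constants are used only to place the
# integration box; the value is computed by brute-force integration of the
# likelihood x prior integrand over (mu, log sigma^2).
quad_loglik_group <- function(x, h) {
  n <- length(x); xb <- mean(x); ss <- sum((x - xb)^2)
  kn <- h$kappa0 + n; nun <- h$nu0 + n
  mun <- (h$kappa0 * h$mu0 + n * xb) / kn
  Sn <- h$nu0 * h$tau20 + ss + h$kappa0 * n / kn * (xb - h$mu0)^2
  ll0 <- marginal_loglik_group(x, h)    # scale factor only
  a <- h$nu0 / 2; b <- h$nu0 * h$tau20 / 2
  u_lo <- log(Sn) - log(qchisq(1e-14, nun, lower.tail = FALSE))
  u_hi <- log(Sn) - log(qchisq(1e-14, nun))
  inner <- function(u) {
    s2 <- exp(u)
    sd_mu <- sqrt(s2 / h$kappa0) + sqrt(s2 / n)
    f <- function(mu)
      exp(vapply(mu, function(m) sum(dnorm(x, m, sqrt(s2), log = TRUE)), 1) +
            dnorm(mu, h$mu0, sqrt(s2 / h$kappa0), log = TRUE) +
            a * log(b) - lgamma(a) - (a + 1) * log(s2) - b / s2 + u - ll0)
    integrate(f, mun - 40 * sd_mu, mun + 40 * sd_mu,
              rel.tol = 1e-12, abs.tol = 0)$value
  }
  q <- integrate(Vectorize(inner), u_lo, u_hi,
                 rel.tol = 1e-12, abs.tol = 0)$value
  ll0 + log(q)
}

# 1-D quadrature of the free-mean marginal (variance integrated out)
quad_loglik_free_mean <- function(x, mu, h) {
  ll0 <- marginal_loglik_free_mean(x, mu, h)
  a <- h$nu0 / 2; b <- h$nu0 * h$tau20 / 2
  g <- function(u) {
    s2 <- exp(u)
    exp(vapply(s2, function(v) sum(dnorm(x, mu, sqrt(v), log = TRUE)), 1) +
          a * log(b) - lgamma(a) - (a + 1) * log(s2) - b / s2 + u - ll0)
  }
  S <- sum((x - mu)^2) + h$nu0 * h$tau20
  nun <- h$nu0 + length(x)
  u_lo <- log(S) - log(qchisq(1e-14, nun, lower.tail = FALSE))
  u_hi <- log(S) - log(qchisq(1e-14, nun))
  q <- integrate(g, u_lo, u_hi, rel.tol = 1e-13, abs.tol = 0)$value
  ll0 + log(q)
}

# draw groups from the hierarchical model's own prior
draw_nix_groups <- function(n_groups, n_per, h) {
  lapply(seq_len(n_groups), function(i) {
    s2 <- h$nu0 * h$tau20 / rchisq(1, h$nu0)
    mu <- rnorm(1, h$mu0, sqrt(s2 / h$kappa0))
    rnorm(n_per, mu, sqrt(s2))
  })
}

# brute-force matcher: per-call nearest-truth scan, per-truth nearest-call
# scan, no vectorisation shared with match_detections
brute_match <- function(calls, truth, tol_bp, same_strand = TRUE) {
  tp <- 0L; fp <- 0L
  for (i in seq_len(nrow(calls))) {
    hit <- FALSE
    for (j in seq_len(nrow(truth))) {
      if (calls$ref_name[i] != truth$ref_name[j]) next
      if (same_strand && calls$strand[i] != truth$strand[j]) next
      if (abs(calls$position[i] - truth$position[j]) <= tol_bp) hit <- TRUE
    }
    if (hit) tp <- tp + 1L else fp <- fp + 1L
  }
  matched <- 0L
  for (j in seq_len(nrow(truth))) {
    for (i in seq_len(nrow(calls))) {
      if (calls$ref_name[i] != truth$ref_name[j]) next
      if (same_strand && calls$strand[i] != truth$strand[j]) next
      if (abs(calls$position[i] - truth$position[j]) <= tol_bp) {
        matched <- matched + 1L
        break
      }
    }
  }
  list(tp = tp, fp = fp, matched_truth = matched)
}

# transform + center a raw table with the simulation's own parameters
prep_table <- function(tab, params) {
  suppressWarnings(normalize_movies(transform_ipd_table(tab, params))$table)
}

# small shared end-to-end fixture (built once per test run)
strong_fixture_env <- new.env()
get_strong_fixture <- function() {
  if (is.null(strong_fixture_env$sim)) {
    sim <- plasmid_fixture("strong_signal_6mA_like", genome_length = 1200L)
    p <- sim$config$transform
    strong_fixture_env$sim <- sim
    strong_fixture_env$native <- prep_table(sim$native, p)
    strong_fixture_env$control <- prep_table(sim$control, p)
    strong_fixture_env$index <- build_context_index(
      prep_table(sim$historical, p), sim$genome, context_window(2L, 1L))
  }
  strong_fixture_env
}
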