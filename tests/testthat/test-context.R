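test_that("context extraction follows the strand-aware window convention", {
  g <- c(chr = "AAGATCAA")
  w61 <- context_window(6L, 1L)
  # window overruns the left contig end
  expect_true(is.na(extract_context(g, "chr", 4L, "+", w61)))
  # minus-strand arithmetic: forward [2,4] = "GAT" -> revcomp "ATC"
  expect_identical(extract_context(g, "chr", 3L, "-", context_window(1L, 1L)),
                   "ATC")
  expect_error(extract_context(g, "nope", 1L, "+", w61), "unknown reference")
  # non-ACGT symbols make the context undefined, not an error
  gn <- c(chr = "AANTCAA")
  expect_true(is.na(extract_context(gn, "chr", 2L, "+", context_window(1L, 1L))))

  # plus/minus extraction with mirrored windows are reverse complements
  set.seed(10)
  rg <- c(r = paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""))
  w <- context_window(3L, 2L)
  wm <- context_window(2L, 3L)   # mirrored
  pos <- 3:194
  plus <- extract_context(rg, "r", pos, "+", w)
  minus_mirror <- extract_context(rg, "r", pos, "-", wm)
  rc <- function(s) chartr("ACGT", "TGCA",
                           vapply(strsplit(s, ""), function(ch)
                             paste(rev(ch), collapse = ""), ""))
  expect_identical(minus_mirror, rc(plus))
})

test_that("the homolog index applies the strict position and coverage thresholds", {
  # constructive table: context of every position of a repeated unit is
  # identical across repeats
  mk_tab <- function(n_pos, cov) {
    ipd_table(data.frame(
      ref_name = "c",
      position = rep(seq_len(n_pos) - 1L, each = cov),
      strand = "+", movie_id = "m",
      ipd = rnorm(n_pos * cov)), scale = "centered")
  }
  # one reference made of the same 8-mer repeated: every (2,1) context
  # recurs once per repeat at the same offset
  unit <- "ACGTGATC"
  genome <- c(c1 = strrep(unit, 12L))
  w <- context_window(2L, 1L)
  set.seed(11)

  # exactly 5 qualifying positions -> excluded; 6 -> included
  pick_ctx <- extract_context(genome, "c1", 19L, "+", w)   # a recurring context
  occs <- which(extract_context(genome, "c1", 0:(nchar(genome) - 1L), "+", w)
                == pick_ctx) - 1L
  tab5 <- ipd_table(data.frame(
    ref_name = "c1", position = rep(occs[1:5], each = 10L), strand = "+",
    movie_id = "m", ipd = rnorm(50)), scale = "centered")
  idx5 <- build_context_index(tab5, genome, w)
  expect_false(pick_ctx %in% names(idx5$entries))
  tab6 <- ipd_table(data.frame(
    ref_name = "c1", position = rep(occs[1:6], each = 10L), strand = "+",
    movie_id = "m", ipd = rnorm(60)), scale = "centered")
  idx6 <- build_context_index(tab6, genome, w)
  expect_true(pick_ctx %in% names(idx6$entries))
  expect_length(idx6$entries[[pick_ctx]], 6L)
  # coverage 9 misses the >= 10 floor
  tab9 <- ipd_table(data.frame(
    ref_name = "c1", position = rep(occs[1:6], each = 9L), strand = "+",
    movie_id = "m", ipd = rnorm(54)), scale = "centered")
  expect_false(pick_ctx %in% names(build_context_index(tab9, genome, w)$entries))

  # empty input -> empty index; raw tables rejected
  empty <- ipd_table(data.frame(ref_name = character(), position = integer(),
                                strand = character(), movie_id = character(),
                                ipd = numeric()), scale = "centered")
  expect_length(build_context_index(empty, genome, w)$entries, 0L)

  # with min_positions = 1, min_cov = 1 the index partitions the positions
  set.seed(12)
  sim <- simulate_dataset(sim_config(genome_length = 120L,
                                     window = context_window(2L, 1L),
                                     coverage_historical = 5L, seed = 12L))
  his <- prep_table(sim$historical, sim$config$transform)
  idx <- build_context_index(his, sim$genome, w, min_cov = 1L,
                             min_positions = 1L)
  n_indexed <- sum(vapply(idx$entries, length, 1L))
  rates <- position_rates(his)
  ctx_all <- extract_context(sim$genome, "chr", rates$position, rates$strand, w)
  expect_equal(n_indexed, sum(!is.na(ctx_all)))
})

test_that("context effects average all member observations, order-invariantly", {
  w <- context_window(1L, 1L)
  genome <- c(a = "TACGT", b = "TACGT")
  t1 <- ipd_table(data.frame(ref_name = "a", position = rep(2L, 2L),
                             strand = "+", movie_id = "m", ipd = c(0, 1)),
                  scale = "centered")
  t2 <- ipd_table(data.frame(ref_name = "b", position = rep(2L, 2L),
                             strand = "+", movie_id = "m", ipd = c(1, 2)),
                  scale = "centered")
  idx <- build_context_index(list(t1, t2), list(genome, genome), w,
                             min_cov = 2L, min_positions = 2L)
  eff <- context_effect(idx)
  expect_equal(eff$effect[eff$context == "ACG"], 1.0)
  expect_equal(eff$n_positions[eff$context == "ACG"], 2L)
  idx_rev <- build_context_index(list(t2, t1), list(genome, genome), w,
                                 min_cov = 2L, min_positions = 2L)
  expect_equal(context_effect(idx_rev)$effect, eff$effect)

  # an index built from a single position reproduces that position's rate
  idx1 <- build_context_index(t1, genome, w, min_cov = 2L,
                              min_positions = 1L)
  expect_equal(context_effect(idx1)$effect, 0.5)
  expect_error(context_effect(build_context_index(t1, genome, w)), "empty")
})

test_that("two independent datasets from one truth give concordant context effects", {
  # one genome and context-effect truth; the two unmodified datasets are
  # independent read draws with independent position deviations
  sim <- simulate_dataset(sim_config(
    genome_length = 1200L, window = context_window(2L, 1L),
    coverage_historical = 40L, coverage_control = 40L,
    position_noise_sd = 0.03,
    modification = list(sites = data.frame(ref_name = character(),
                                           position = integer(),
                                           strand = character())),
    seed = 21L))
  his1 <- prep_table(sim$historical, sim$config$transform)
  his2 <- prep_table(sim$control, sim$config$transform)
  w <- context_window(2L, 1L)
  e1 <- context_effect(build_context_index(his1, sim$genome, w,
                                           min_cov = 10L, min_positions = 4L))
  e2 <- context_effect(build_context_index(his2, sim$genome, w,
                                           min_cov = 10L, min_positions = 4L))
  shared <- intersect(e1$context, e2$context)
  expect_gt(length(shared), 50L)
  expect_gt(cor(e1$effect[match(shared, e1$context)],
                e2$effect[match(shared, e2$context)]), 0.95)
})

test_that("context regression recovers predictable responses and rejects noise", {
  set.seed(13)
  bases <- c("A", "C", "G", "T")
  # a 3-base context recurs often enough for the trees to memorise the
  # lookup exactly
  ctxs <- vapply(1:1500, function(i)
    paste(sample(bases, 3L, TRUE), collapse = ""), "")
  lookup <- setNames(rnorm(length(unique(ctxs))), unique(ctxs))
  y_pred <- unname(lookup[ctxs])
  fit <- fit_context_regression(y_pred, ctxs, nrounds = 600L)
  expect_gt(fit$cv_r2, 0.95)

  # context-independent response: no spurious held-out skill (light
  # boosting; heavier boosting only drifts further below zero)
  y_noise <- rnorm(1500)
  fit_n <- fit_context_regression(y_noise, ctxs, nrounds = 100L)
  expect_gt(fit_n$cv_r2, -0.05)
  expect_lt(fit_n$cv_r2, 0.05)

  fit_c <- fit_context_regression(rep(1, 1500), ctxs)
  expect_equal(fit_c$cv_r2, 0)
  expect_error(fit_context_regression(rnorm(100), ctxs[1:100]), ">= 500")

  # row-permutation invariance given the fixed fold seed
  perm <- sample(1500)
  fit_p <- fit_context_regression(y_pred[perm], ctxs[perm], nrounds = 600L)
  expect_lt(abs(fit_p$cv_r2 - fit$cv_r2), 0.02)
})
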