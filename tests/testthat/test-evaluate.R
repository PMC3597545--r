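test_that("detection matching applies the inclusive +/-5 bp rule", {
  truth <- truth_set(data.frame(ref_name = "c", position = 100L,
                                strand = "+"))
  at5 <- data.frame(ref_name = "c", position = 105L, strand = "+")
  at6 <- data.frame(ref_name = "c", position = 106L, strand = "+")
  m5 <- match_detections(at5, truth)
  expect_equal(m5$tp, 1L)          # exactly 5 bp away: still a hit
  m6 <- match_detections(at6, truth)
  expect_equal(m6$fp, 1L)
  # strand mismatch is not a hit under the same-strand default
  wrong <- data.frame(ref_name = "c", position = 100L, strand = "-")
  expect_equal(match_detections(wrong, truth)$tp, 0L)
  expect_equal(match_detections(wrong, truth, same_strand = FALSE)$tp, 1L)

  # two flanking calls, one truth site: both are TPs, one matched site
  both <- data.frame(ref_name = "c", position = c(97L, 103L), strand = "+")
  mb <- match_detections(both, truth)
  expect_equal(mb$tp, 2L)
  expect_equal(mb$matched_truth, 1L)
  expect_equal(mb$tpr, 1)
  expect_equal(mb$fdr, 0)
})

test_that("matching agrees with a brute-force matcher on random instances", {
  set.seed(16)
  for (i in 1:8) {
    truth <- truth_set(data.frame(
      ref_name = sample(c("a", "b"), 50L, TRUE),
      position = sample(0:400, 50L),
      strand = sample(c("+", "-"), 50L, TRUE)))
    calls <- data.frame(
      ref_name = sample(c("a", "b"), 60L, TRUE),
      position = sample(0:400, 60L, TRUE),
      strand = sample(c("+", "-"), 60L, TRUE))
    tol <- sample(0:8, 1L)
    fast <- match_detections(calls, truth, tol_bp = tol)
    slow <- brute_match(calls, truth, tol)
    expect_equal(fast$tp, slow$tp)
    expect_equal(fast$fp, slow$fp)
    expect_equal(fast$matched_truth, slow$matched_truth)
  }
})

test_that("FDR and TPR are monotone along the threshold sweep", {
  set.seed(17)
  truth <- truth_set(data.frame(ref_name = "c",
                                position = seq(10L, 190L, by = 20L),
                                strand = "+"))
  sc <- data.frame(ref_name = "c", position = 0:199, strand = "+",
                   score = rnorm(200), stringsAsFactors = FALSE)
  # boost truth-site scores so the curve is non-trivial
  sc$score[sc$position %in% truth$position] <-
    sc$score[sc$position %in% truth$position] + 3
  curve <- roc_curve(sc, truth)
  expect_true(all(diff(curve$tpr) >= 0))   # thresholds sweep descending
  expect_true(all(curve$fdr >= 0 & curve$fdr <= 1))
  expect_true(all(curve$tpr >= 0 & curve$tpr <= 1))
})

test_that("score AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(18)
  truth <- truth_set(data.frame(ref_name = "c", position = c(5L, 50L, 80L),
                                strand = "+"))
  sc <- data.frame(ref_name = "c", position = 0:99, strand = "+",
                   score = rnorm(100) + 2 * (0:99 %in% truth$position),
                   stringsAsFactors = FALSE)
  lab <- as.integer(sc$position %in% truth$position)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc$score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(score_auc(sc, truth), ref)
})

test_that("subsampling reduces to the plain ROC at full coverage and checks targets", {
  fx <- get_strong_fixture()
  truth <- fx$sim$truth
  nat_small <- fx$native[fx$native$position < 300L, ]
  attr(nat_small, "scale") <- "centered"; class(nat_small) <- class(fx$native)
  scorer <- function(nat, ctl) scan_genome(nat, ctl, method = "case_control")
  cov_full <- fx$sim$config$coverage_native
  set.seed(19)
  sub <- roc_by_subsampling(nat_small, fx$control, truth,
                            list(c(native = cov_full, control = NA)),
                            n_rep = 1L, scorer = scorer,
                            tpr_grid = c(0.25, 0.5))
  full_curve <- roc_curve(scorer(nat_small, fx$control), truth)
  for (k in seq_len(nrow(sub))) {
    ok <- which(full_curve$tpr >= sub$tpr[k])
    expect_equal(sub$fdr[k], full_curve$fdr[ok[1L]])
  }
  expect_error(
    roc_by_subsampling(nat_small, NULL, truth,
                       list(c(native = cov_full + 5L, control = NA)),
                       n_rep = 1L, scorer = scorer),
    "exceeds coverage")
})

test_that("motif FDR counts off-motif significant calls at the cognate base", {
  genome <- c(c = "AAGATCAAAGATCAAA")
  sites <- motif_sites(genome, "GATC", 1L)
  plus <- sites[sites$strand == "+", ]
  expect_setequal(plus$position, c(3L, 10L))
  # palindromic motif: minus-strand adenines sit at the T offset
  expect_true(all(c(4L, 11L) %in% sites$position[sites$strand == "-"]))

  mk_scores <- function(pos, strand, score)
    data.frame(ref_name = "c", position = pos, strand = strand,
               score = score, stringsAsFactors = FALSE)
  # all significant adenine calls inside the motif -> FDR 0
  expect_equal(motif_fdr(mk_scores(c(3L, 10L), "+", 5), genome, "GATC", 1L,
                         threshold = 1), 0)
  # all outside (adenines at 0,1) -> FDR 1
  expect_equal(motif_fdr(mk_scores(c(0L, 1L), "+", 5), genome, "GATC", 1L,
                         threshold = 1), 1)
  # non-adenine calls are ignored entirely
  expect_equal(motif_fdr(mk_scores(c(3L, 5L), "+", 5), genome, "GATC", 1L,
                         threshold = 1), 0)   # position 5 is C, not counted
  expect_warning(f <- motif_fdr(mk_scores(3L, "+", 5), genome, "TTTTTT", 1L,
                                threshold = 1), "not found")
  expect_true(is.na(f))
})

test_that("neighbourhood restriction is inclusive and anchor-driven", {
  sc <- data.frame(ref_name = "c", position = c(0L, 20L, 21L, 50L),
                   strand = "+", score = 1, stringsAsFactors = FALSE)
  anchors <- data.frame(ref_name = "c", position = 0L)
  expect_equal(restrict_to_neighborhoods(sc, anchors, 0L)$position, 0L)
  expect_equal(restrict_to_neighborhoods(sc, anchors, 20L)$position,
               c(0L, 20L))          # exactly radius away is kept
  none <- restrict_to_neighborhoods(sc, anchors[integer(), , drop = FALSE])
  expect_equal(nrow(none), 0L)
})

test_that("empirical FDR is the WGA-to-native call ratio", {
  nat <- data.frame(ref_name = "c", position = 0:9, strand = "+",
                    score = c(rep(5, 8), 0, 0))
  wga <- data.frame(ref_name = "c", position = 0:9, strand = "+",
                    score = c(rep(5, 2), rep(0, 8)))
  expect_equal(empirical_fdr(nat, wga, 1), 0.25)
  expect_true(is.na(empirical_fdr(nat, wga, 10)))
})
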