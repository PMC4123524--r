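random_maps <- function(seed, n = 3, M = 8, N = 8, density = 0.25) {
  set.seed(seed)
  lapply(seq_len(n), function(i) matrix(runif(M * N) < density, M, N))
}

test_that("potential ground truths follow the vote rule and nest", {
  m <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_true(all(mapply(identical, potential_ground_truths(list(m, m, m)),
                         list(m, m, m))))

  # two disjoint maps: level 1 is the union, level 2 empty
  a <- matrix(FALSE, 3, 3); a[1, ] <- TRUE
  b <- matrix(FALSE, 3, 3); b[3, ] <- TRUE
  pg <- potential_ground_truths(list(a, b))
  expect_identical(pg[[1]], a | b)
  expect_identical(sum(pg[[2]]), 0L)

  # 2x2 grid with vote counts {3, 2, 1, 0} across three maps
  m1 <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  m2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  m3 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  pg3 <- potential_ground_truths(list(m1, m2, m3))
  expect_identical(pg3[[2]], matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))

  # nesting on random instances
  for (seed in 1:50) {
    pg <- potential_ground_truths(random_maps(seed))
    for (i in seq_along(pg)[-1]) expect_true(all(pg[[i - 1]][pg[[i]]]))
  }
  expect_error(potential_ground_truths(list(a)), "at least 2")
  expect_error(potential_ground_truths(list(a, matrix(TRUE, 2, 2))), "share one shape")
})

test_that("correspondence rates reproduce hand-computed confusions", {
  pgt <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  map <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  r <- correspondence_rates(list(map), pgt)
  expect_equal(r$tpr, 0.5)
  expect_equal(r$fpr, 0.5)
  expect_equal(r$tpr + r$fnr, 1)
  expect_equal(r$fpr + r$tnr, 1)

  rid <- correspondence_rates(list(pgt), pgt)
  expect_equal(c(rid$tpr, rid$fpr), c(1, 0))
  rcomp <- correspondence_rates(list(!pgt), pgt)
  expect_equal(c(rcomp$tpr, rcomp$fpr), c(0, 1))

  # degenerate reference: rates reported as 0 with a flag, no error
  rdeg <- correspondence_rates(list(map), matrix(FALSE, 2, 2))
  expect_true(rdeg$degenerate)
  expect_identical(rdeg$tpr, 0)
})

test_that("the CT-ROC matches an independent per-level recomputation", {
  for (seed in 1:10) {
    maps <- random_maps(seed)
    roc <- ct_roc(maps)
    votes <- Reduce(`+`, lapply(maps, function(m) m * 1))
    for (lvl in 1:3) {
      ref <- votes >= lvl
      tprs <- fprs <- numeric(0)
      for (m in maps) {
        pos <- sum(ref); neg <- sum(!ref)
        tprs <- c(tprs, if (pos > 0) sum(m & ref) / pos else 0)
        fprs <- c(fprs, if (neg > 0) sum(m & !ref) / neg else 0)
      }
      expect_equal(roc$TPR[lvl], mean(tprs))
      expect_equal(roc$FPR[lvl], mean(fprs))
    }
    # as the level rises the reference shrinks toward the intersection, so
    # map pixels outside it can only grow: FPR is nondecreasing, and TPR is
    # nondecreasing (surviving positives are shared by more maps); levels
    # with an empty reference report flagged zeros and are excluded
    nd <- !roc$degenerate
    expect_true(all(diff(roc$FPR[nd]) >= -1e-12))
    expect_true(all(diff(roc$TPR[nd]) >= -1e-12))
    # level 1 reference is the union of the maps: no false positives
    expect_equal(roc$FPR[1], 0)
  }
  # identical maps: every nondegenerate level sits at (0, 1)
  m <- random_maps(1, n = 1)[[1]]
  roc_id <- ct_roc(list(m, m, m))
  expect_true(all(roc_id$FPR == 0))
  expect_true(all(roc_id$TPR[!roc_id$degenerate] == 1))
})

test_that("ground-truth estimation and best-map selection behave on canonical cases", {
  m <- random_maps(2, n = 1, density = 0.3)[[1]]
  gt <- estimate_ground_truth(list(m, m, m))
  expect_identical(gt$level, 1L)
  expect_identical(gt$mask, m)
  sel <- select_best_map(list(m, m, m))
  expect_identical(as.integer(sel), 1L)

  # N = 2 equal maps
  gt2 <- estimate_ground_truth(list(m, m))
  expect_identical(gt2$level, 1L)
  expect_identical(gt2$mask, m)

  # one sloppy map = union of the tight ones plus many extra pixels:
  # consensus should move past level 1
  set.seed(77)
  tight <- matrix(FALSE, 12, 12); tight[6, 2:11] <- TRUE
  sloppy <- tight | matrix(runif(144) < 0.45, 12, 12)
  gt3 <- estimate_ground_truth(list(tight, tight, tight, sloppy))
  expect_gt(gt3$level, 1L)
  expect_identical(gt3$mask, tight)
  expect_identical(as.integer(select_best_map(list(sloppy, tight, tight, tight))), 2L)
})

test_that("selection is invariant to input order and exact-match candidates win", {
  for (seed in 1:10) {
    maps <- random_maps(seed, n = 4, M = 10, N = 10)
    gt <- estimate_ground_truth(maps)
    perm <- sample(length(maps))
    gtp <- estimate_ground_truth(maps[perm])
    expect_identical(gtp$mask, gt$mask)
    sel <- select_best_map(maps)
    selp <- select_best_map(maps[perm])
    expect_identical(maps[perm][[as.integer(selp)]], maps[[as.integer(sel)]])
  }
  # the selected map maximizes a hand-computed F1 against the estimated truth
  maps <- random_maps(4, n = 3, M = 10, N = 10)
  gt <- estimate_ground_truth(maps)
  hand_f1 <- vapply(maps, function(m) {
    tp <- sum(m & gt$mask); fp <- sum(m & !gt$mask); fn <- sum(!m & gt$mask)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  expect_identical(as.integer(select_best_map(maps)), which.max(hand_f1))
  # a candidate identical to the common map of an identical family is selected
  sel_id <- select_best_map(list(maps[[1]], maps[[1]]))
  expect_identical(maps[[as.integer(sel_id)]], maps[[1]])
})

test_that("yitzhaky_rank reports per-candidate rates and the selected map", {
  maps <- random_maps(6, n = 3, M = 10, N = 10)
  names(maps) <- c("a", "b", "c")
  tab <- yitzhaky_rank(maps)
  expect_identical(tab$candidate_id, c("a", "b", "c"))
  expect_identical(sum(tab$selected), 1L)
  expect_true(all(tab$TPR >= 0 & tab$TPR <= 1))
  expect_true(all(tab$F1 >= 0 & tab$F1 <= 1))
  expect_identical(which(tab$selected), as.integer(select_best_map(unname(maps))))
})
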