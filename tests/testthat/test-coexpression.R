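test_that("PCC matrix matches the textbook two-pass oracle", {
  set.seed(5)
  lnc <- expr_matrix(matrix(rnorm(4 * 5, 6, 2), 4, 5),
                     paste0("l", 1:4), paste0("s", 1:5))
  gx <- expr_matrix(matrix(rnorm(6 * 5, 6, 2), 6, 5),
                    paste0("g", 1:6), paste0("s", 1:5))
  r <- pcc_matrix(lnc, gx)
  two_pass <- function(a, b) {
    am <- mean(a); bm <- mean(b)
    sum((a - am) * (b - bm)) / sqrt(sum((a - am)^2) * sum((b - bm)^2))
  }
  for (i in 1:4) for (j in 1:6)
    expect_equal(r[i, j], two_pass(unclass(lnc)[i, ], unclass(gx)[j, ]),
                 tolerance = 1e-12)
  expect_true(all(r >= -1 & r <= 1))
})

test_that("PCC handles identical, negated and constant profiles", {
  v <- c(1, 3, 2, 5, 4)
  lnc <- expr_matrix(rbind(v, -v + 10, rep(2, 5)),
                     c("same", "neg", "flat"), paste0("s", 1:5))
  gx <- expr_matrix(rbind(v), "g1", paste0("s", 1:5))
  r <- pcc_matrix(lnc, gx)
  expect_equal(r["same", "g1"], 1)
  expect_equal(r["neg", "g1"], -1)
  expect_equal(r["flat", "g1"], 0)
  expect_true(attr(r, "zero_variance")["flat", "g1"])

  small <- expr_matrix(matrix(1:4, 2, 2), c("a", "b"), c("s1", "s2"))
  expect_error(pcc_matrix(small, small), ">= 3 samples")
})

test_that("PCC is symmetric in the pair and invariant to positive affine maps", {
  set.seed(6)
  a <- expr_matrix(matrix(rnorm(10), 1, 10), "a", paste0("s", 1:10))
  b <- expr_matrix(matrix(rnorm(10), 1, 10), "b", paste0("s", 1:10))
  expect_equal(pcc_matrix(a, b)[1, 1], pcc_matrix(b, a)[1, 1])
  a2 <- expr_matrix(unclass(a) * 3.7 + 1.2, "a", paste0("s", 1:10))
  expect_equal(pcc_matrix(a2, b)[1, 1], pcc_matrix(a, b)[1, 1],
               tolerance = 1e-12)
})

test_that("training-set labels follow the PCC thresholds", {
  set.seed(7)
  lnc <- expr_matrix(matrix(rnorm(2 * 6), 2, 6), c("l1", "l2"), paste0("s", 1:6))
  gx <- expr_matrix(matrix(rnorm(2 * 6), 2, 6), c("g1", "g2"), paste0("s", 1:6))
  pcc <- matrix(c(0.9, 0.0, 0.5, -0.8), 2, 2, byrow = TRUE,
                dimnames = list(c("l1", "l2"), c("g1", "g2")))
  ds <- build_training_set(pcc, lnc, gx, pipeline_config())
  expect_equal(ds$n_pos, 1)
  expect_equal(ds$n_neg, 1)
  pos <- ds$pairs[ds$y > 0, ]
  expect_equal(unname(unlist(pos)), c("l1", "g1"))
  neg <- ds$pairs[ds$y < 0, ]
  expect_equal(unname(unlist(neg)), c("l1", "g2"))
  # features are lncRNA profile then gene profile
  expect_equal(ds$x[1, ], c(unclass(lnc)["l1", ], unclass(gx)["g1", ]),
               ignore_attr = TRUE)
  expect_equal(ncol(ds$x), 2 * 6)
})

test_that("negative subsampling is deterministic in the seed only", {
  b <- simulate_cohort(n_patients = 60, seed = 8)
  al <- align_samples(b$lnc, b$genes)
  pcc <- pcc_matrix(al$lnc, al$mrna)
  cfg <- test_config()
  ds1 <- build_training_set(pcc, al$lnc, al$mrna, cfg, seed = 4)
  ds2 <- build_training_set(pcc, al$lnc, al$mrna, cfg, seed = 4)
  ds3 <- build_training_set(pcc, al$lnc, al$mrna, cfg, seed = 5)
  expect_identical(ds1$pairs, ds2$pairs)
  expect_identical(ds1$pairs[ds1$y > 0, ], ds3$pairs[ds3$y > 0, ])
  expect_equal(ds3$n_neg, ds3$n_pos)
})

test_that("impossible training sets raise advisory errors", {
  lnc <- expr_matrix(matrix(rnorm(12), 2, 6), c("l1", "l2"), paste0("s", 1:6))
  gx <- expr_matrix(matrix(rnorm(12), 2, 6), c("g1", "g2"), paste0("s", 1:6))
  pcc_lo <- matrix(0.1, 2, 2, dimnames = list(rownames(lnc), rownames(gx)))
  expect_error(build_training_set(pcc_lo, lnc, gx, pipeline_config()),
               "relaxing pos_pcc_threshold")
  pcc_hi <- matrix(0.9, 2, 2, dimnames = list(rownames(lnc), rownames(gx)))
  expect_error(build_training_set(pcc_hi, lnc, gx, pipeline_config()),
               "raising neg_pcc_threshold")
})

test_that("the SVM separates a separable toy set and flips with the labels", {
  ds <- toy_pair_dataset(seed = 9)
  grid1 <- list(C = 1, gamma = 0.05)
  fit <- train_svm(ds, grid = grid1, seed = 1, tolerance = 1e-8)
  pred <- decision_values(fit, ds$x)
  expect_true(all(sign(pred$f) == ds$y))

  flipped <- ds; flipped$y <- -ds$y
  fit2 <- train_svm(flipped, grid = grid1, seed = 1, tolerance = 1e-8)
  pred2 <- decision_values(fit2, ds$x)
  expect_equal(pred2$f, -pred$f, tolerance = 1e-5)
})

test_that("dual feasibility holds for the trained model", {
  ds <- toy_pair_dataset(seed = 10)
  fit <- train_svm(ds, grid = list(C = 2, gamma = 0.05), seed = 1,
                   tolerance = 1e-8)
  expect_true(all(fit$alpha >= -1e-8 & fit$alpha <= fit$C + 1e-8))
  expect_lt(abs(sum(fit$alpha * ds$y)), 1e-6)
})

test_that("single-class training input is rejected", {
  ds <- toy_pair_dataset(n_neg = 0, seed = 11)
  expect_error(train_svm(ds), "single class")
  expect_error(evaluate_cv(ds), "single class")
})

test_that("calibrated scores are in [0,1] and monotone in decision values", {
  b <- simulate_cohort(n_patients = 80, seed = 12)
  al <- align_samples(b$lnc, b$genes)
  pcc <- pcc_matrix(al$lnc, al$mrna)
  ds <- build_training_set(pcc, al$lnc, al$mrna, test_config(), seed = 12)
  fit <- train_svm(ds, seed = 12)
  am <- score_pairs(fit, al$lnc, al$mrna)
  expect_true(all(am$s >= 0 & am$s <= 1))
  ord <- order(am$f)
  expect_true(all(diff(am$s[ord]) >= 0))
  expect_identical(dim(am$f), dim(am$s))
})

test_that("planted pairs score high and independent pairs low", {
  b <- simulate_cohort(seed = 13)
  al <- align_samples(b$lnc, b$genes)
  pcc <- pcc_matrix(al$lnc, al$mrna)
  ds <- build_training_set(pcc, al$lnc, al$mrna, test_config(), seed = 13)
  fit <- train_svm(ds, seed = 13)
  am <- score_pairs(fit, al$lnc, al$mrna)
  blk <- b$truth$blocks[[2]]
  expect_true(all(am$s[blk$lncRNA, blk$up_genes] > 0.9))
  null_block <- am$s[setdiff(am$lncRNA_ids, vapply(b$truth$blocks, `[[`,
                                                   "", "lncRNA")),
                     setdiff(am$gene_ids, b$truth$coexpressed_pairs$gene_id)]
  expect_lt(mean(null_block), 0.5)
})

test_that("feature-dimension mismatches are caught when scoring", {
  ds <- toy_pair_dataset(seed = 14)
  # small folds can defeat the calibration fit; only the dimension check matters
  fit <- suppressWarnings(train_svm(ds, grid = list(C = 1, gamma = 0.05),
                                    seed = 1))
  expect_error(decision_values(fit, ds$x[, 1:10]), "does not match")
})

test_that("confusion metrics reproduce the hand-computed example", {
  m <- confusion_metrics(tp = 8, fn = 2, tn = 5, fp = 5)
  expect_equal(m$sn, 0.8)
  expect_equal(m$sp, 0.5)
  expect_equal(m$acc, 0.65)
  expect_equal(m$pre, 8 / 13, tolerance = 1e-10)
  expect_equal(m$pre, 0.6154, tolerance = 1e-4)
  expect_equal(m$f_measure, sqrt(0.8 * 0.5), tolerance = 1e-10)
  expect_equal(m$f_measure, 0.6325, tolerance = 1e-4)
})

test_that("rank metrics behave at their extremes and under the null", {
  scores <- c(0.9, 0.8, 0.3, 0.2)
  labels <- c(1, 1, -1, -1)
  expect_equal(auc_score(scores, labels), 1)
  expect_equal(aupr_score(scores, labels), 1)
  set.seed(15)
  s <- runif(4000); y <- rep(c(1, -1), 2000)
  expect_equal(auc_score(s, y), 0.5, tolerance = 0.03)
})

test_that("cross-validated metrics are near-perfect on a strong-signal cohort", {
  b <- simulate_cohort(n_patients = 120, seed = 16)
  al <- align_samples(b$lnc, b$genes)
  pcc <- pcc_matrix(al$lnc, al$mrna)
  ds <- build_training_set(pcc, al$lnc, al$mrna, test_config(), seed = 16)
  cv <- evaluate_cv(ds, seed = 16)
  expect_gte(cv$auc, 0.95)
  expect_gte(cv$aupr, 0.95)
  expect_equal(cv$f_measure, sqrt(cv$sn * cv$sp), tolerance = 1e-12)
  for (k in c("auc", "aupr", "acc", "sn", "sp", "pre", "f_measure"))
    expect_true(cv[[k]] >= 0 && cv[[k]] <= 1)
})
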