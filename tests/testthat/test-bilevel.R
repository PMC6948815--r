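mk_sig <- function(cc) {
  structure(list(gene_ids = names(cc), c = cc), class = "drug_signature")
}
mk_assoc <- function(f, s = NULL) {
  structure(list(f = f, s = if (is.null(s)) plogis(f) else s,
                 lncRNA_ids = rownames(f), gene_ids = colnames(f)),
            class = "assoc_matrix")
}

test_that("the closed-form upper solution reproduces hand examples", {
  # weighted mean of constants is the constant
  cc <- c(g1 = 0.4, g2 = 0.4, g3 = 0.4)
  f <- matrix(0.7, 2, 3, dimnames = list(c("l1", "l2"), names(cc)))
  expect_equal(unname(upper_solution(mk_sig(cc), mk_assoc(f))), c(0.7, 0.7))

  # c = (1, -1), f column (0.8, 0.3) -> (0.8 - 0.3) / 2
  cc2 <- c(g1 = 1, g2 = -1)
  f2 <- matrix(c(0.8, 0.3), 1, 2, dimnames = list("l1", names(cc2)))
  expect_equal(unname(upper_solution(mk_sig(cc2), mk_assoc(f2))), 0.25)

  # zero-coefficient genes contribute nothing
  cc3 <- c(g1 = 1, g2 = -1, g3 = 0)
  f3 <- matrix(c(0.8, 0.3, 99), 1, 3, dimnames = list("l1", names(cc3)))
  expect_equal(unname(upper_solution(mk_sig(cc3), mk_assoc(f3))), 0.25)

  expect_error(upper_solution(mk_sig(c(g1 = 0, g2 = 0)), mk_assoc(f3)),
               "empty signature")
})

test_that("closed form agrees with the zero-initialised numeric minimiser", {
  set.seed(17)
  for (rep in 1:5) {
    n_g <- 40; n_l <- 12
    cc <- setNames(runif(n_g, -1, 1), paste0("g", 1:n_g))
    f <- matrix(rnorm(n_l * n_g), n_l, n_g,
                dimnames = list(paste0("l", 1:n_l), names(cc)))
    d_closed <- upper_solution(cc, f)
    d_num <- upper_solution_numeric(cc, f)
    expect_equal(d_closed, d_num, tolerance = 1e-6)
  }
})

test_that("d respects the weighted-mean envelope and invariances", {
  set.seed(18)
  n_g <- 30; n_l <- 8
  cc <- setNames(runif(n_g, -1, 1), paste0("g", 1:n_g))
  cc[sample(n_g, 3)] <- 0
  f <- matrix(rnorm(n_l * n_g), n_l, n_g,
              dimnames = list(paste0("l", 1:n_l), names(cc)))
  d <- upper_solution(cc, f)
  nz <- names(cc)[cc != 0]
  signed <- sweep(f[, nz], 2, sign(cc[nz]), "*")
  expect_true(all(d >= apply(signed, 1, min) - 1e-12))
  expect_true(all(d <= apply(signed, 1, max) + 1e-12))

  # positive rescaling of c leaves d unchanged
  expect_equal(upper_solution(3.7 * cc, f), d, tolerance = 1e-12)

  # linearity in f: a*f + b shifts d by a*d + b * sum(c)/sum(|c|)
  a <- 2.5; b <- -0.7
  d2 <- upper_solution(cc, a * f + b)
  expect_equal(d2, a * d + b * sum(cc) / sum(abs(cc)), tolerance = 1e-12)
})

test_that("ranking sorts by descending d with identifier tie-break", {
  d <- c(lB = 0.5, lA = 0.5, lC = 0.9, lD = 0.1)
  p <- c(lA = 0.01, lB = 0.01, lC = 0.01, lD = 0.01)
  sel <- rank_and_select(d, top_k = 3, selection_pvalue = 0.05, empirical_p = p)
  expect_identical(sel, c("lC", "lA", "lB"))

  # p filter empties the selection
  p1 <- p; p1[] <- 1
  expect_length(rank_and_select(d, 3, 0.05, p1), 0)

  # all pass, top_k limits
  expect_identical(rank_and_select(d, 1, 0.05, p), "lC")
})

test_that("empirical specificity p is the top-list frequency with a floor", {
  lists <- c(list(c("l1", "l2")), replicate(28, c("l2", "l3"), simplify = FALSE))
  p <- empirical_pvalue(lists, lncRNA_ids = c("l1", "l2", "l3", "l9"))
  expect_equal(unname(p["l1"]), 1 / 29)
  expect_equal(unname(p["l2"]), 1)
  expect_equal(unname(p["l3"]), 28 / 29)
  # never listed: floored at 1/n_drugs, strictly positive
  expect_equal(unname(p["l9"]), 1 / 29)
  expect_true(all(p > 0 & p <= 1))
  expect_error(empirical_pvalue(list()), "empty drug panel")

  two_of_29 <- empirical_pvalue(
    c(replicate(2, "lx", simplify = FALSE),
      replicate(27, "ly", simplify = FALSE)), "lx")
  expect_equal(unname(two_of_29), 2 / 29, tolerance = 1e-12)
})

test_that("overlap counts enumerate genes passing both thresholds", {
  cc <- c(g1 = 0.95, g2 = -0.92, g3 = 0.91, g4 = 0.5, g5 = -0.1)
  s <- matrix(c(0.95, 0.99, 0.2, 0.99, 0.99), 1, 5,
              dimnames = list("l1", names(cc)))
  sig <- mk_sig(cc); am <- mk_assoc(log(s / (1 - s)), s)
  cfg <- pipeline_config()
  # g1 and g2 pass both filters; g3 fails the score, g4/g5 fail on |c|
  expect_equal(overlap_count(sig, am, "l1", cfg), 2)
  cfg_lo <- pipeline_config(assoc_score_threshold = 0.1)
  expect_equal(overlap_count(sig, am, "l1", cfg_lo), 3)
  expect_error(overlap_count(sig, am, "l99", cfg), "unknown lncRNA")
})

test_that("rank score follows the mid-rank percentile formula", {
  uniform <- setNames(rep(4L, 7), paste0("l", 1:7))
  rs <- rank_score(uniform, "l3")
  expect_equal(rs$rs, 50)
  expect_equal(rs$f_b, 0); expect_equal(rs$f_w, 7)

  maximal <- setNames(c(10L, rep(3L, 99)), paste0("l", 1:100))
  rs2 <- rank_score(maximal, "l1")
  expect_equal(rs2$rs, 99.5)

  minimal <- setNames(c(0L, rep(5L, 9)), paste0("l", 1:10))
  rs3 <- rank_score(minimal, "l1")
  expect_equal(rs3$rs, 5)
  expect_gte(rs3$f_w, 1)
})

test_that("rank score is permutation-invariant and monotone in own overlap", {
  set.seed(19)
  ov <- setNames(sample(0:8, 30, replace = TRUE), paste0("l", 1:30))
  rs <- rank_score(ov, "l7")
  perm <- c("l7", sample(setdiff(names(ov), "l7")))
  expect_equal(rank_score(ov[perm], "l7")$rs, rs$rs)

  ov_up <- ov; ov_up["l7"] <- ov["l7"] + 1L
  expect_gt(rank_score(ov_up, "l7")$rs, rs$rs)
})

test_that("associate_drugs assembles a coherent association table", {
  b <- simulate_bundle(n_patients = 120, seed = 20)
  cfg <- test_config(20)
  res <- run_pipeline(b, cfg, quiet = TRUE)
  tab <- as.data.frame(res$association)
  expect_identical(colnames(tab),
                   c("drug", "lncRNA", "d", "rank", "empirical_p", "selected",
                     "RS", "n_overlap_genes"))
  expect_equal(nrow(tab), 3 * 50)
  for (dn in unique(tab$drug)) {
    sub <- tab[tab$drug == dn, ]
    expect_identical(sub$rank, 1:50)
    expect_true(all(diff(sub$d) <= 1e-12))
  }
  expect_true(all(tab$empirical_p > 0 & tab$empirical_p <= 1))
  cm <- coef(res$association)
  expect_equal(dim(cm), c(50, 3))
})
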