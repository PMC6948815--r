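test_that("drug panel selection is strictly 'more than' the instance cutoff", {
  tt <- data.frame(
    instance_id = sprintf("i%02d", 1:25),
    drug_name = c(rep("dEleven", 11), rep("dTen", 10), rep("vehicle", 4)),
    group = c(rep("treated", 21), rep("control", 4)))
  expect_identical(select_drugs(tt, 10), "dEleven")
  expect_identical(select_drugs(tt, 9), c("dEleven", "dTen"))
  empty <- tt[tt$group == "control", ]
  expect_identical(select_drugs(empty, 10), character(0))
})

test_that("Welch p-values match the per-gene t.test oracle to 1e-10", {
  set.seed(11)
  expr <- expr_matrix(matrix(rnorm(50 * 12, 6, 1), 50, 12),
                      paste0("g", 1:50), paste0("i", 1:12))
  treated <- paste0("i", 1:6); control <- paste0("i", 7:12)
  de <- differential_expression(expr, treated, control)
  oracle <- vapply(1:50, function(i) {
    tt <- t.test(unclass(expr)[i, treated], unclass(expr)[i, control])
    c(tt$p.value, unname(tt$estimate[1] - tt$estimate[2]))
  }, numeric(2))
  expect_equal(de$pvalue, oracle[1, ], tolerance = 1e-10)
  expect_equal(de$logFC, oracle[2, ], tolerance = 1e-12)
  expect_equal(de$adj_pvalue, p.adjust(de$pvalue, "BH"))
})

test_that("differential expression handles degenerate and invalid groups", {
  vals <- matrix(rep(c(1, 2, 3), each = 8), 3, 8, byrow = TRUE)
  expr <- expr_matrix(vals, paste0("g", 1:3), paste0("i", 1:8))
  de <- differential_expression(expr, paste0("i", 1:4), paste0("i", 5:8))
  expect_equal(de$logFC, rep(0, 3))
  expect_equal(de$pvalue, rep(1, 3))

  expect_error(differential_expression(expr, paste0("i", 1:4),
                                       paste0("i", 4:8)), "overlap")
  expect_error(differential_expression(expr, "i1", paste0("i", 5:8)),
               ">= 2 instances")
})

test_that("planted shifted genes attain the smallest adjusted p-values", {
  set.seed(21)
  n_g <- 200; shifted <- paste0("g", 1:20)
  vals <- matrix(rnorm(n_g * 30, 6, 0.5), n_g, 30,
                 dimnames = list(paste0("g", 1:n_g), paste0("i", 1:30)))
  vals[shifted, 1:15] <- vals[shifted, 1:15] + 2
  expr <- expr_matrix(vals)
  de <- differential_expression(expr, paste0("i", 1:15), paste0("i", 16:30))
  top20 <- de$gene_id[order(de$adj_pvalue)][1:20]
  expect_setequal(top20, shifted)
})

test_that("signature coefficients reproduce the three-gene hand computation", {
  de <- data.frame(gene_id = c("a", "b", "c"),
                   logFC = c(1, -2, 0.5),
                   pvalue = c(0.01, 0.001, 0.5),
                   adj_pvalue = c(0.01, 0.001, 0.5))
  sg <- signature_coefficients(de)
  expect_equal(unname(sg$sig), c(2, 6, 0.5 * (-log10(0.5))), tolerance = 1e-12)
  expect_equal(unname(sg$c), c(0.3162, -1, 0), tolerance = 1e-4)
  expect_equal(sg$mu, min(sg$sig))
  expect_equal(sg$nu, 6)
})

test_that("signature coefficient invariants hold over random DE tables", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(3:40, 1)
    de <- data.frame(gene_id = paste0("g", 1:n),
                     logFC = round(rnorm(n), 2),
                     pvalue = runif(n),
                     adj_pvalue = runif(n))
    sg <- signature_coefficients(de)
    expect_true(all(sg$c >= -1 & sg$c <= 1))
    if (sg$nu > sg$mu) {
      expect_setequal(unname(which(abs(sg$c) == 1)),
                      unname(which(sg$sig == sg$nu)))
    }
    expect_true(all(sg$c[de$logFC == 0] == 0))

    # min-max normalisation: invariant under positive affine maps of sig,
    # realised by scaling |logFC| and leaving p fixed
    a <- runif(1, 0.5, 3)
    de2 <- de; de2$logFC <- de$logFC * a
    expect_equal(signature_coefficients(de2)$c, sg$c, tolerance = 1e-12,
                 ignore_attr = TRUE)

    # permuting gene order permutes c identically
    perm <- sample(n)
    sg_p <- signature_coefficients(de[perm, ])
    expect_equal(unname(sg_p$c), unname(sg$c[perm]))
  }
})

test_that("degenerate signatures are all-zero with a warning", {
  de <- data.frame(gene_id = c("a", "b"), logFC = c(0, 0),
                   pvalue = c(1, 1), adj_pvalue = c(1, 1))
  expect_warning(sg <- signature_coefficients(de), "degenerate")
  expect_equal(unname(sg$c), c(0, 0))
})

test_that("drug_signatures pools instances per drug and exposes coef matrix", {
  b <- simulate_bundle(n_patients = 40, seed = 3)
  sigs <- drug_signatures(b$instances, b$treatments, test_config())
  expect_s3_class(sigs, "drug_signature_set")
  expect_length(sigs, 3)
  cm <- coef(sigs)
  expect_equal(dim(cm), c(200, 3))
  expect_true(all(cm >= -1 & cm <= 1))
  # planted signature genes carry the largest |c|
  for (dn in names(sigs)) {
    tr <- b$truth$drugs[[dn]]
    planted <- c(tr$up_genes, tr$down_genes)
    top10 <- names(sort(abs(sigs[[dn]]$c), decreasing = TRUE))[1:10]
    expect_gte(length(intersect(top10, planted)), 9)
    expect_true(all(sigs[[dn]]$c[tr$up_genes] > 0))
    expect_true(all(sigs[[dn]]$c[tr$down_genes] < 0))
  }
})
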