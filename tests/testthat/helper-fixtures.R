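# shared fixtures, all built in code

# tiny well-formed expression matrix
tiny_expr <- function(nf = 3, ns = 2, seed = 42) {
  set.seed(seed)
  expr_matrix(matrix(round(runif(nf * ns, 0, 12), 3), nf, ns),
              feature_ids = paste0("f", seq_len(nf)),
              sample_ids = paste0("s", seq_len(ns)))
}

# small labeled pair dataset with clear class structure, for SVM tests:
# positives share a latent factor across the two halves, negatives are noise
toy_pair_dataset <- function(n_pos = 6, n_neg = 6, n_samples = 20, seed = 1) {
  set.seed(seed)
  mk_pos <- function() {
    z <- rnorm(n_samples)
    c(z + rnorm(n_samples, 0, 0.3), z + rnorm(n_samples, 0, 0.3))
  }
  mk_neg <- function() rnorm(2 * n_samples)
  rows <- c(lapply(seq_len(n_pos), function(i) mk_pos()),
            lapply(seq_len(n_neg), function(i) mk_neg()))
  x <- do.call(rbind, rows)
  structure(list(pairs = data.frame(lncRNA_id = paste0("l", seq_len(n_pos + n_neg)),
                                    gene_id = paste0("g", seq_len(n_pos + n_neg)),
                                    stringsAsFactors = FALSE),
                 x = x, y = c(rep(1, n_pos), rep(-1, n_neg)),
                 n_samples = n_samples, n_pos = n_pos, n_neg = n_neg),
            class = "pair_dataset")
}

# default synthetic-cohort analysis settings used across tests
test_config <- function(seed = 1) synthetic_config(rng_seed = seed)
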