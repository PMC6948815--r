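#' Simulate a patient cohort with planted coexpression blocks
#'
#' Latent-factor model: each of `n_blocks` blocks holds one lncRNA and
#' `block_size` genes that all load on one standard-normal patient factor.
#' A planted profile is `baseline + loading * z + residual`, with the
#' loading and residual variance solving
#' `loading^2 / (loading^2 + residual_sd^2) = signal_rho` under the side
#' condition `loading^2 + residual_sd^2 = noise_sd^2`: the expected
#' pairwise Pearson correlation of two planted profiles is exactly
#' `signal_rho`, while every feature — planted or not — keeps the same
#' marginal variance, so coexpression is carried by the joint pattern
#' only, never by a marginal-variance shortcut a classifier could exploit.
#' Half of each block's genes load positively
#' ("up" genes, PCC `+signal_rho` with the block lncRNA) and half
#' negatively ("down" genes, PCC `-signal_rho`): a drug perturbing the
#' block pushes the two halves in opposite directions, which is what makes
#' the signed signature informative downstream.  All remaining features
#' are independent noise around `baseline`.  Values are clipped into the
#' log2-like range `[0, 12]`.
#'
#' @param n_patients,n_lnc,n_genes cohort dimensions.
#' @param n_blocks,block_size planted coexpression blocks (one lncRNA and
#'   `block_size` genes each; needs `n_blocks <= n_lnc` and
#'   `n_blocks * block_size <= n_genes`).
#' @param signal_rho target pairwise PCC of planted pairs, in `[0, 1)`.
#' @param noise_sd standard deviation of the independent noise.
#' @param baseline centre of the expression range.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return List with `lnc`, `genes` (both `expr_matrix`) and `truth`, a
#'   list holding `blocks` (per block: `lncRNA`, `up_genes`, `down_genes`),
#'   `coexpressed_pairs` (data.frame with signed target PCC) and the
#'   generator parameters.
#' @export
simulate_cohort <- function(n_patients = 200, n_lnc = 50, n_genes = 200,
                            n_blocks = 3, block_size = 10, signal_rho = 0.8,
                            noise_sd = 1, baseline = 4, seed = 1) {
  if (signal_rho < 0 || signal_rho >= 1) stop("signal_rho must lie in [0, 1)")
  if (n_blocks > n_lnc) stop("more blocks than lncRNAs")
  if (n_blocks * block_size > n_genes)
    stop("infeasible block allocation: n_blocks * block_size > n_genes")
  if (min(n_patients, n_lnc, n_genes, block_size) < 1)
    stop("all dimensions must be positive")
  with_seed(seed, {
    lnc_ids <- sprintf("lnc%03d", seq_len(n_lnc))
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    patients <- sprintf("P%03d", seq_len(n_patients))
    loading <- noise_sd * sqrt(signal_rho)
    resid_sd <- noise_sd * sqrt(1 - signal_rho)
    lnc_vals <- matrix(stats::rnorm(n_lnc * n_patients, baseline, noise_sd),
                       n_lnc, n_patients, dimnames = list(lnc_ids, patients))
    gene_vals <- matrix(stats::rnorm(n_genes * n_patients, baseline, noise_sd),
                        n_genes, n_patients, dimnames = list(gene_ids, patients))
    blocks <- vector("list", n_blocks)
    pair_rows <- list()
    for (b in seq_len(n_blocks)) {
      z <- stats::rnorm(n_patients)
      g_idx <- ((b - 1) * block_size + 1):(b * block_size)
      n_up <- ceiling(block_size / 2)
      sign_vec <- rep(c(1, -1), c(n_up, block_size - n_up))
      lnc_vals[b, ] <- baseline + loading * z +
        stats::rnorm(n_patients, 0, resid_sd)
      gene_vals[g_idx, ] <- baseline + tcrossprod(sign_vec * loading, z) +
        matrix(stats::rnorm(block_size * n_patients, 0, resid_sd),
               block_size, n_patients)
      blocks[[b]] <- list(lncRNA = lnc_ids[b],
                          up_genes = gene_ids[g_idx[sign_vec > 0]],
                          down_genes = gene_ids[g_idx[sign_vec < 0]])
      pair_rows[[b]] <- data.frame(lncRNA_id = lnc_ids[b],
                                   gene_id = gene_ids[g_idx],
                                   target_pcc = sign_vec * signal_rho,
                                   stringsAsFactors = FALSE)
    }
    clip <- function(m) pmin(pmax(m, 0), 12)
    list(lnc = expr_matrix(clip(lnc_vals)),
         genes = expr_matrix(clip(gene_vals)),
         truth = list(blocks = blocks,
                      coexpressed_pairs = do.call(rbind, pair_rows),
                      signal_rho = signal_rho, noise_sd = noise_sd,
                      baseline = baseline, seed = seed))
  })
}

#' Simulate a treated-vs-control instance panel
#'
#' One drug per cohort block: control instances are baseline noise, and a
#' drug's treated instances shift the block's "up" genes by `+effect` and
#' its "down" genes by `-effect`.  The drug's planted signature genes thus
#' coincide with one block's gene set, making the block's lncRNA the
#' drug's linked lncRNA by construction.  A shared control pool (drug name
#' `vehicle`) serves all drugs.
#'
#' @param gene_ids gene identifiers of the panel (superset of all block
#'   genes).
#' @param blocks `truth$blocks` from [simulate_cohort()]; drug `k` is
#'   planted on block `k`.
#' @param instances_per_drug treated instances per drug (and size of the
#'   shared control pool); keep above 10 so the default panel filter
#'   retains the drugs.
#' @param effect expression shift of the planted signature genes.
#' @param noise_sd instance noise standard deviation.
#' @param baseline control expression level.
#' @param seed integer seed.
#' @return List with `instances` (`expr_matrix`, genes x instances),
#'   `treatments` (design table) and `truth` (per drug: `up_genes`,
#'   `down_genes`, `linked_lncRNA`, `effect`).
#' @export
simulate_treatments <- function(gene_ids, blocks, instances_per_drug = 15,
                                effect = 2, noise_sd = 0.5, baseline = 4,
                                seed = 1) {
  n_drugs <- length(blocks)
  if (n_drugs == 0) stop("no blocks to plant drugs on")
  all_genes <- unlist(lapply(blocks, function(b) c(b$up_genes, b$down_genes)))
  if (anyDuplicated(all_genes))
    stop("blocks share planted genes; disjoint sets required")
  if (!all(all_genes %in% gene_ids))
    stop("block genes missing from gene_ids")
  with_seed(seed, {
    drugs <- sprintf("drug%02d", seq_len(n_drugs))
    n_inst <- n_drugs * instances_per_drug + instances_per_drug
    inst_ids <- sprintf("I%04d", seq_len(n_inst))
    vals <- matrix(stats::rnorm(length(gene_ids) * n_inst, baseline, noise_sd),
                   length(gene_ids), n_inst,
                   dimnames = list(gene_ids, inst_ids))
    design <- data.frame(instance_id = inst_ids,
                         drug_name = "vehicle", group = "control",
                         stringsAsFactors = FALSE)
    truth <- list()
    for (k in seq_len(n_drugs)) {
      cols <- ((k - 1) * instances_per_drug + 1):(k * instances_per_drug)
      design$drug_name[cols] <- drugs[k]
      design$group[cols] <- "treated"
      vals[blocks[[k]]$up_genes, cols] <- vals[blocks[[k]]$up_genes, cols] + effect
      vals[blocks[[k]]$down_genes, cols] <- vals[blocks[[k]]$down_genes, cols] - effect
      truth[[drugs[k]]] <- list(up_genes = blocks[[k]]$up_genes,
                                down_genes = blocks[[k]]$down_genes,
                                linked_lncRNA = blocks[[k]]$lncRNA,
                                effect = effect)
    }
    list(instances = expr_matrix(vals), treatments = design, truth = truth)
  })
}

#' Simulate survival records tied to one lncRNA's expression group
#'
#' Exponential event times whose rate is multiplied by `hazard_ratio` for
#' patients in the high-expression group (expression strictly above
#' `high`); independent exponential censoring tuned to an approximate
#' overall censoring fraction.
#'
#' @param values named expression values of the target lncRNA (names are
#'   patient ids).
#' @param hazard_ratio event-rate multiplier for high-expression patients
#'   (> 1 means worse prognosis when highly expressed).
#' @param censor_rate target fraction of censored patients, in `[0, 1)`.
#' @param base_rate baseline event rate (per unit follow-up time).
#' @param high threshold defining the high-expression group.
#' @param seed integer seed.
#' @return Survival `data.frame` with `patient_id`, `time`, `event`.
#' @export
simulate_survival <- function(values, hazard_ratio = 3, censor_rate = 0.2,
                              base_rate = 0.02, high = 6, seed = 1) {
  if (hazard_ratio <= 0) stop("hazard_ratio must be positive")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must lie in [0, 1)")
  with_seed(seed, {
    n <- length(values)
    rate <- ifelse(values > high, base_rate * hazard_ratio, base_rate)
    t_event <- stats::rexp(n, rate)
    if (censor_rate > 0) {
      c_rate <- mean(rate) * censor_rate / (1 - censor_rate)
      t_cens <- stats::rexp(n, c_rate)
    } else {
      t_cens <- rep(Inf, n)
    }
    data.frame(patient_id = names(values),
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete input bundle
#'
#' Cohort, treatment panel and survival records with one consistent ground
#' truth, ready for [run_pipeline()].  The survival effect is tied to the
#' first block's lncRNA.
#'
#' @param n_patients,n_lnc,n_genes,n_blocks,block_size,signal_rho,noise_sd
#'   passed to [simulate_cohort()].
#' @param instances_per_drug,effect,instance_noise_sd passed to
#'   [simulate_treatments()] (one drug per block).
#' @param hazard_ratio,censor_rate passed to [simulate_survival()].
#' @param survival_high expression threshold above which the target
#'   lncRNA raises the hazard; the default of 5 is one marginal standard
#'   deviation above the default baseline of 4, so roughly the top sixth
#'   of patients carry the elevated hazard.  Analyses of such a cohort
#'   should dichotomize around matching per-lncRNA thresholds (e.g. high
#'   > 5, low < 3) rather than the 6/2 defaults that suit full-range
#'   clinical data.
#' @param seed integer master seed (stage seeds are derived from it).
#' @return List with `lnc`, `genes`, `instances`, `treatments`,
#'   `survival`, and `truth` combining all planted structure.
#' @export
simulate_bundle <- function(n_patients = 200, n_lnc = 50, n_genes = 200,
                            n_blocks = 3, block_size = 10, signal_rho = 0.8,
                            noise_sd = 1, instances_per_drug = 15,
                            effect = 2, instance_noise_sd = 0.5,
                            hazard_ratio = 3, censor_rate = 0.2,
                            survival_high = 5, seed = 1) {
  seed <- as.integer(seed)
  cohort <- simulate_cohort(n_patients, n_lnc, n_genes, n_blocks, block_size,
                            signal_rho, noise_sd, seed = seed)
  panel <- simulate_treatments(rownames(cohort$genes), cohort$truth$blocks,
                               instances_per_drug, effect, instance_noise_sd,
                               seed = (seed + 101L) %% .Machine$integer.max)
  target <- cohort$truth$blocks[[1]]$lncRNA
  surv <- simulate_survival(unclass(cohort$lnc)[target, ], hazard_ratio,
                            censor_rate, high = survival_high,
                            seed = (seed + 202L) %% .Machine$integer.max)
  list(lnc = cohort$lnc, genes = cohort$genes, instances = panel$instances,
       treatments = panel$treatments, survival = surv,
       truth = c(cohort$truth, list(drugs = panel$truth,
                                    survival_lncRNA = target,
                                    hazard_ratio = hazard_ratio)))
}

#' Write a simulated bundle to a directory
#'
#' Emits `lnc_expression.tsv`, `gene_expression.tsv`, `instances.tsv`,
#' `treatments.tsv`, `survival.tsv` and a `truth.yaml` sidecar describing
#' the planted structure.
#'
#' @param bundle a [simulate_bundle()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(bundle$lnc, file.path(dir, "lnc_expression.tsv"),
                       id_column = "lncRNA_id")
  write_expression_tsv(bundle$genes, file.path(dir, "gene_expression.tsv"),
                       id_column = "gene_id")
  write_expression_tsv(bundle$instances, file.path(dir, "instances.tsv"),
                       id_column = "gene_id")
  utils::write.table(bundle$treatments, file.path(dir, "treatments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_survival_tsv(bundle$survival, file.path(dir, "survival.tsv"))
  truth <- bundle$truth
  truth$coexpressed_pairs <- as.list(truth$coexpressed_pairs)
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Read a simulated bundle back from a directory
#'
#' @param dir directory written by [write_bundle()].
#' @return List with `lnc`, `genes`, `instances`, `treatments`,
#'   `survival` (no truth: the sidecar is for inspection, not for the
#'   pipeline).
#' @export
read_bundle <- function(dir) {
  list(lnc = read_expression_tsv(file.path(dir, "lnc_expression.tsv")),
       genes = read_expression_tsv(file.path(dir, "gene_expression.tsv")),
       instances = read_expression_tsv(file.path(dir, "instances.tsv")),
       treatments = read_treatment_table(file.path(dir, "treatments.tsv")),
       survival = if (file.exists(file.path(dir, "survival.tsv")))
         read_survival_tsv(file.path(dir, "survival.tsv")))
}
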