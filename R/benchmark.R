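#' Oracle-support prior for a simulated truth
#'
#' Applies the study-style prior construction rule to a known ground truth:
#' the support (nonzero prior probability) consists of the true edges (the
#' stand-in for known canonical interactions) plus edges from every directly
#' perturbed node to every other node; all remaining edges are hard-excluded.
#' Within the support the prior is uninformative (`pi` everywhere), so
#' posterior edge probabilities are driven by the data, not the prior weight.
#'
#' @param truth A `gt_network`.
#' @param design A `perturbation_design`.
#' @param pi Prior inclusion probability on the support, default 0.5.
#' @return A `prior_network`.
#' @export
support_prior <- function(truth, design, pi = 0.5) {
  te <- tidy(truth)
  perturbed <- unique(design$target)
  grid <- expand_grid(from = truth$node_names, to = truth$node_names) |>
    filter(.data$from != .data$to) |>
    mutate(prior_prob = ifelse(
      paste(.data$from, .data$to) %in% paste(te$from, te$to) |
        .data$from %in% perturbed,
      pi, 0))
  structure(grid, class = c("prior_network", class(grid)))
}

#' Area under the ROC of posterior edge probabilities against a known truth
#'
#' Ranks every candidate (off-diagonal) edge by its posterior probability and
#' computes the probability that a randomly chosen true edge outranks a
#' randomly chosen non-edge (the Wilcoxon form of the AUROC, ties counted
#' half).
#'
#' @param fit A `bmra_fit`.
#' @param truth The `gt_network` the data were simulated from.
#' @return AUROC in \[0, 1\].
#' @export
edge_recovery_auc <- function(fit, truth) {
  ed <- tidy(fit)
  te <- tidy(truth)
  labels <- paste(ed$from, ed$to) %in% paste(te$from, te$to)
  scores <- ifelse(is.na(ed$posterior_prob), 0, ed$posterior_prob)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("AUROC needs both true edges and non-edges.")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Edge-recovery benchmark on simulated perturbation studies
#'
#' For each seed: draws a ground-truth network, simulates a replicate-level
#' RPPA dataset under the perturbation design, runs the full fold-change ->
#' lumping -> network-inference path, and scores posterior edge probabilities
#' against the truth by AUROC. The prior is the oracle-support prior
#' ([support_prior()]): exclusions are correct, but the prior carries no
#' preference among admitted edges.
#'
#' @param seeds Integer seeds, one simulated study per seed.
#' @param n_nodes,edge_density,strength_range,noise_sd Ground-truth
#'   parameters (defaults: the 18-node panel at density 0.2, strengths in
#'   \[0.3, 1\], replicate noise 0.05).
#' @param design Perturbation design; default [tnbc_design()] (requires the
#'   18-node panel).
#' @param config A [bmra_config()]; the default uses a vague coefficient
#'   prior (g = 50), which sharpens model selection in this underdetermined
#'   design (see the methods vignette).
#' @return Tibble with `seed` and `auroc`.
#' @export
edge_recovery_benchmark <- function(seeds = 1:10, n_nodes = 18,
                                    edge_density = 0.2,
                                    strength_range = c(0.3, 1),
                                    noise_sd = 0.05,
                                    design = tnbc_design(),
                                    config = bmra_config(g = 50)) {
  res <- map(seeds, function(s) {
    truth <- generate_network(n_nodes, edge_density, strength_range,
                              noise_sd = noise_sd, seed = s)
    node_map <- if (n_nodes == 18) tnbc_node_map() else NULL
    ds <- emit_dataset(truth, design, node_map = node_map,
                       seed = s + 7919L)
    fc <- compute_log2_foldchanges(ds$analyte_table)
    if (!is.null(node_map)) fc <- lump_nodes(fc, node_map)
    cfg <- config
    cfg$seed <- as.integer(s)
    fit <- suppressWarnings(
      infer_network(fc, design, prior = support_prior(truth, design),
                    config = cfg)
    )
    tibble(seed = s, auroc = edge_recovery_auc(fit, truth))
  })
  list_rbind(res)
}
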