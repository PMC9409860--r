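#' Compute treatment-induced log2 fold changes from a replicate-level table
#'
#' For every (cell line, treatment, analyte), the fold change is the mean of
#' the log2-transformed treated replicate values minus the mean of the
#' log2-transformed control replicates, and the p-value comes from a Welch
#' two-sample t-test on the log2 replicate values. Working on the log scale
#' makes up- and down-regulation symmetric.
#'
#' @param table Data frame with columns `cell_line`, `treatment`, `replicate`,
#'   `analyte`, `value` (positive measurements; a `"control"` treatment must
#'   be present for every cell line, each condition with >= 2 replicates).
#' @param alpha Significance level for the `significant` flag, default 0.05.
#' @return A `fold_change_tbl`: tibble with `cell_line`, `treatment`, `node`
#'   (initially the analyte identifier), `log2_fc`, `p_value`, `significant`,
#'   carrying `alpha` as an attribute. Control rows are not included.
#' @examples
#' ds <- emit_dataset(generate_network(4, 0.3, seed = 1),
#'   perturbation_design(data.frame(treatment = "tx", target = "N1", effect = 1)))
#' compute_log2_foldchanges(ds$analyte_table)
#' @export
compute_log2_foldchanges <- function(table, alpha = 0.05) {
  table <- as_tibble(table)
  req <- c("cell_line", "treatment", "replicate", "analyte", "value")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols)) {
    abort(paste0("Analyte table is missing columns: ", toString(missing_cols)))
  }
  if (any(!is.finite(table$value) | table$value <= 0)) {
    abort("All measurement values must be positive and finite.")
  }
  no_ctrl <- table |>
    summarise(has_ctrl = any(.data$treatment == "control"), .by = "cell_line") |>
    filter(!.data$has_ctrl)
  if (nrow(no_ctrl)) {
    abort(paste0("No control condition for cell line(s): ",
                 toString(no_ctrl$cell_line)))
  }

  logt <- table |> mutate(log2_value = log2(.data$value))
  n_reps <- logt |>
    count(.data$cell_line, .data$treatment, .data$analyte) |>
    filter(.data$n < 2)
  if (nrow(n_reps)) {
    abort(paste0("Conditions with fewer than 2 replicates, e.g. ",
                 n_reps$cell_line[1], "/", n_reps$treatment[1], "/",
                 n_reps$analyte[1]))
  }

  ctrl <- logt |>
    filter(.data$treatment == "control") |>
    summarise(ctrl_values = list(.data$log2_value),
              .by = c("cell_line", "analyte"))

  out <- logt |>
    filter(.data$treatment != "control") |>
    summarise(values = list(.data$log2_value),
              .by = c("cell_line", "treatment", "analyte")) |>
    inner_join(ctrl, by = c("cell_line", "analyte")) |>
    mutate(
      log2_fc = map_dbl(.data$values, mean) - map_dbl(.data$ctrl_values, mean),
      p_value = purrr::map2_dbl(.data$values, .data$ctrl_values, welch_p)
    ) |>
    transmute(
      .data$cell_line, .data$treatment, node = .data$analyte,
      .data$log2_fc, .data$p_value,
      significant = .data$p_value < alpha
    )
  new_fold_change_tbl(out, alpha = alpha)
}

# Welch t-test p-value; degenerate zero-variance comparisons fall back to
# p = 1 when the means agree and p = 0 when they do not.
welch_p <- function(x, y) {
  if (sd(x) == 0 && sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
}

new_fold_change_tbl <- function(x, alpha) {
  structure(as_tibble(x), alpha = alpha,
            class = c("fold_change_tbl", class(as_tibble(x))))
}

#' @export
print.fold_change_tbl <- function(x, ...) {
  cat(sprintf("# fold changes (alpha = %g)\n", attr(x, "alpha")))
  NextMethod()
}

#' Lump phospho-site analytes into network nodes
#'
#' Collapses analytes that measure the same protein module into a single node
#' by averaging their log2 fold changes (and combining p-values by Fisher's
#' method so the significance flag survives lumping). Single-analyte nodes
#' pass through unchanged. Modules on the same protein share information flow
#' in the modular-response view, so they form one network node.
#'
#' @param fc A `fold_change_tbl` whose `node` column still holds analyte ids.
#' @param map Tibble with columns `analyte`, `node` covering every analyte in
#'   `fc`; default `tnbc_node_map()`.
#' @return A `fold_change_tbl` keyed by lumped node.
#' @export
lump_nodes <- function(fc, map = tnbc_node_map()) {
  alpha <- attr(fc, "alpha") %||% 0.05
  missing_analytes <- setdiff(unique(fc$node), map$analyte)
  if (length(missing_analytes)) {
    abort(paste0("Analytes absent from the node map: ",
                 toString(missing_analytes)))
  }
  out <- fc |>
    inner_join(map, by = c(node = "analyte"), suffix = c("", ".map")) |>
    summarise(
      log2_fc = mean(.data$log2_fc),
      p_value = fisher_p(.data$p_value),
      .by = c("cell_line", "treatment", "node.map")
    ) |>
    rename(node = "node.map") |>
    mutate(significant = .data$p_value < alpha)
  new_fold_change_tbl(out, alpha = alpha)
}

# Fisher's combined p; a single p passes through unchanged.
fisher_p <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  if (length(p) == 1) return(p)
  p <- pmax(p, .Machine$double.xmin)
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Count significant node changes per treatment
#'
#' Tallies, for each cell line and treatment, how many nodes change
#' significantly (p below the table's alpha), and the mean absolute log2 fold
#' change per node, which ranks overall cell-line responsiveness.
#'
#' @param fc A `fold_change_tbl` (lumped or not).
#' @param treatment Optional treatment identifier(s) to restrict to.
#' @return Tibble with `cell_line`, `treatment`, `n_significant`,
#'   `mean_abs_log2_fc`.
#' @export
count_significant_changes <- function(fc, treatment = NULL) {
  if (!is.null(treatment)) {
    unknown <- setdiff(treatment, unique(fc$treatment))
    if (length(unknown)) {
      abort(paste0("Unknown treatment(s): ", toString(unknown)))
    }
    fc <- fc |> filter(.data$treatment %in% .env$treatment)
  }
  fc |>
    summarise(
      n_significant = sum(.data$significant, na.rm = TRUE),
      mean_abs_log2_fc = mean(abs(.data$log2_fc)),
      .by = c("cell_line", "treatment")
    ) |>
    arrange(.data$cell_line, desc(.data$n_significant))
}

#' Pivot a fold-change table to a node x treatment response matrix
#'
#' @param fc A `fold_change_tbl` for a single cell line (or filtered to one).
#' @param cell_line Optional cell line to select when several are present.
#' @return Numeric matrix, nodes x treatments, of log2 fold changes — the
#'   global response matrix used by network inference.
#' @export
response_matrix <- function(fc, cell_line = NULL) {
  if (!is.null(cell_line)) fc <- fc |> filter(.data$cell_line == .env$cell_line)
  lines <- unique(fc$cell_line)
  if (length(lines) != 1) {
    abort("Fold-change table spans several cell lines; pass `cell_line`.")
  }
  wide <- fc |>
    select("node", "treatment", "log2_fc") |>
    pivot_wider(names_from = "treatment", values_from = "log2_fc")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$node
  m
}

#' Hierarchically cluster fold-change response profiles
#'
#' Agglomerative clustering of rows of a fold-change matrix with Euclidean
#' distance and average linkage, the standard choice for heat-map ordering of
#' perturbation-response profiles.
#'
#' @param x A `fold_change_tbl` (single cell line) or a numeric matrix whose
#'   rows are observations to cluster.
#' @param ... Passed to [response_matrix()] when `x` is a fold-change table.
#' @return An [stats::hclust] object.
#' @export
cluster_responses <- function(x, ...) {
  m <- if (is.matrix(x)) x else response_matrix(x, ...)
  if (nrow(m) < 2) abort("Need at least 2 rows to cluster.")
  if (anyNA(m)) abort("Response matrix contains NA; impute or drop upstream.")
  hclust(dist(m, method = "euclidean"), method = "average")
}
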