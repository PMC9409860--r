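#' Generate a random ground-truth signalling network
#'
#' Draws an n-node network of local response coefficients for use as a known
#' truth when validating network inference. Off-diagonal entries are nonzero
#' with probability `edge_density`; nonzero strengths are drawn uniformly from
#' `strength_range` with a random sign. The diagonal is fixed at -1 (the
#' modular-response-analysis normalisation: each node's self-effect is the
#' reference against which incoming edges are measured). Matrices that come
#' out numerically singular are redrawn, up to `max_tries` attempts.
#'
#' @param n_nodes Number of network nodes (>= 2).
#' @param edge_density Probability that an ordered off-diagonal pair carries
#'   an edge, in (0, 1); 0 is allowed and yields the empty network.
#' @param strength_range Length-2 numeric, the magnitude range for nonzero
#'   local response coefficients.
#' @param noise_sd Replicate noise standard deviation (log2 scale) carried
#'   along for downstream simulation.
#' @param node_names Optional node identifiers; defaults to `tnbc_nodes()`
#'   when `n_nodes == 18`, else `"N1"..."Nn"`.
#' @param seed Integer RNG seed; the same seed always returns the same network.
#' @param max_tries Redraw budget for singular matrices.
#'
#' @return A `gt_network`: list with `node_names`, `local_response` (n x n
#'   matrix, diagonal -1), `noise_sd`, `seed`.
#' @examples
#' net <- generate_network(6, edge_density = 0.3, seed = 1)
#' net$local_response
#' @export
generate_network <- function(n_nodes, edge_density, strength_range = c(0.3, 1),
                             noise_sd = 0.05, node_names = NULL, seed = 1L,
                             max_tries = 100L) {
  if (n_nodes < 2) abort("`n_nodes` must be >= 2.")
  if (edge_density < 0 || edge_density > 1) {
    abort("`edge_density` must be in [0, 1].")
  }
  if (is.null(node_names)) {
    node_names <- if (n_nodes == 18) tnbc_nodes() else paste0("N", seq_len(n_nodes))
  }
  stopifnot(length(node_names) == n_nodes, !anyDuplicated(node_names))

  r <- withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      m <- matrix(0, n_nodes, n_nodes)
      off <- which(row(m) != col(m))
      present <- runif(length(off)) < edge_density
      k <- sum(present)
      if (k > 0) {
        mag <- runif(k, strength_range[1], strength_range[2])
        sgn <- sample(c(-1, 1), k, replace = TRUE)
        m[off[present]] <- mag * sgn
      }
      diag(m) <- -1
      if (abs(det(m)) > 1e-12) break
      m <- NULL
    }
    m
  })
  if (is.null(r)) {
    abort(sprintf("No invertible local response matrix found in %d tries.", max_tries))
  }
  dimnames(r) <- list(node_names, node_names)
  structure(
    list(node_names = node_names, local_response = r,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "gt_network"
  )
}

#' @export
print.gt_network <- function(x, ...) {
  n_edges <- sum(x$local_response != 0) - length(x$node_names)
  cat(sprintf("<gt_network> %d nodes, %d edges, noise_sd = %g, seed = %d\n",
              length(x$node_names), n_edges, x$noise_sd, x$seed))
  invisible(x)
}

#' Tidy a ground-truth network into an edge list
#' @param x A `gt_network`.
#' @param ... Unused.
#' @return Tibble with `from`, `to`, `strength` for each nonzero off-diagonal
#'   local response coefficient (`to` is the affected node).
#' @export
tidy.gt_network <- function(x, ...) {
  r <- x$local_response
  idx <- which(r != 0 & row(r) != col(r), arr.ind = TRUE)
  tibble(
    from = x$node_names[idx[, "col"]],
    to = x$node_names[idx[, "row"]],
    strength = r[idx]
  ) |>
    arrange(.data$from, .data$to)
}

#' The 18 network nodes of the default TNBC panel
#'
#' Phosphoprotein modules measured by the RPPA panel after lumping
#' multi-site analytes: the MAPK cascade (RAF, MEK, ERK), the PI3K-AKT axis
#' (PI3K, PTEN, PDK1, AKT, mTOR, GSK3B, p70S6K, S6RIB), energy signalling
#' (AMPK), stress/DNA-damage signalling (p38, CHK1, p53), and NFkB, STAT3,
#' FAK.
#' @return Character vector of 18 node names.
#' @export
tnbc_nodes <- function() {
  c("RAF", "MEK", "ERK", "PI3K", "PTEN", "PDK1", "AKT", "mTOR", "GSK3B",
    "AMPK", "p70S6K", "S6RIB", "NFkB", "CHK1", "p38", "p53", "STAT3", "FAK")
}

#' Default analyte-to-node map for the TNBC RPPA panel
#'
#' Maps 21 phospho-site analytes to 18 network nodes. Sites on the same
#' protein are lumped into one module: AKT S473 + T308 -> AKT,
#' mTOR S2448 + S2481 -> mTOR, S6 ribosomal protein S235 + S240 -> S6RIB.
#' All other analytes map one-to-one.
#' @return Tibble with columns `analyte`, `node`.
#' @export
tnbc_node_map <- function() {
  tribble(
    ~analyte,      ~node,
    "RAF_S338",    "RAF",
    "MEK_S217",    "MEK",
    "ERK_T202",    "ERK",
    "PI3Kalpha",   "PI3K",
    "PTEN",        "PTEN",
    "PDK1_S241",   "PDK1",
    "AKT_S473",    "AKT",
    "AKT_T308",    "AKT",
    "mTOR_S2448",  "mTOR",
    "mTOR_S2481",  "mTOR",
    "GSK3B_S9",    "GSK3B",
    "AMPK_T172",   "AMPK",
    "p70S6K_T389", "p70S6K",
    "S6RIB_S235",  "S6RIB",
    "S6RIB_S240",  "S6RIB",
    "NFkB_p65",    "NFkB",
    "CHK1_S345",   "CHK1",
    "p38_T180",    "p38",
    "p53",         "p53",
    "STAT3_Y705",  "STAT3",
    "FAK_Y925",    "FAK"
  )
}

#' Default 12-treatment perturbation design for the TNBC panel
#'
#' One row per (treatment, targeted node) with the signed direct-effect
#' magnitude on log2 scale. Inhibitors act negatively on their design target;
#' AICAR, an AMPK activator, acts positively. QNZ appears at two doses
#' (1000 and 5000 nM) as two distinct treatments with the same target and
#' dose-scaled magnitudes. Cisplatin, a DNA-damaging agent with no measured
#' molecular target, is mapped as a positive direct perturbation of the
#' DNA-damage transducers CHK1 and p53.
#'
#' @param effect Base direct-effect magnitude (log2 units), default 1.
#' @param replicates Replicates per condition, default 4.
#' @return A `perturbation_design`: tibble with `treatment`, `target`,
#'   `effect` and a `replicates` attribute.
#' @export
tnbc_design <- function(effect = 1, replicates = 4L) {
  d <- tribble(
    ~treatment,     ~target,  ~sign, ~scale,
    "ipatasertib",  "AKT",    -1,    1,
    "AICAR",        "AMPK",   +1,    1,
    "dorsomorphin", "AMPK",   -1,    1,
    "TAK632",       "RAF",    -1,    1,
    "PF00562271",   "FAK",    -1,    1,
    "CHIR98014",    "GSK3B",  -1,    1,
    "U0126",        "MEK",    -1,    1,
    "everolimus",   "mTOR",   -1,    1,
    "QNZ_1000",     "NFkB",   -1,    0.5,
    "QNZ_5000",     "NFkB",   -1,    1,
    "PF4708671",    "p70S6K", -1,    1,
    "cisplatin",    "CHK1",   +1,    1,
    "cisplatin",    "p53",    +1,    1
  ) |>
    mutate(effect = .data$sign * .data$scale * effect) |>
    select("treatment", "target", "effect")
  perturbation_design(d, replicates = replicates)
}

#' Construct a perturbation design
#'
#' @param map Data frame with columns `treatment`, `target`, `effect`
#'   (one row per directly targeted node; `effect` is the signed log2-scale
#'   direct effect).
#' @param replicates Replicates per condition (>= 2).
#' @return A `perturbation_design` tibble.
#' @export
perturbation_design <- function(map, replicates = 4L) {
  map <- as_tibble(map)
  stopifnot(all(c("treatment", "target", "effect") %in% names(map)))
  if (any(map$effect == 0)) abort("Direct effects must be nonzero.")
  if (replicates < 2) abort("`replicates` must be >= 2.")
  structure(map, replicates = as.integer(replicates),
            class = c("perturbation_design", class(map)))
}

design_treatments <- function(design) unique(design$treatment)

design_replicates <- function(design) attr(design, "replicates") %||% 4L

#' Direct-effect (sensitivity) matrix of a design
#'
#' Expands a perturbation design into the n x m matrix S with `S[i, k]` the
#' signed direct effect of treatment k on node i (0 for untargeted nodes).
#' @param design A `perturbation_design`.
#' @param node_names Node identifiers (rows of S).
#' @return Numeric matrix, nodes x treatments.
#' @export
design_matrix <- function(design, node_names) {
  bad <- setdiff(design$target, node_names)
  if (length(bad)) {
    abort(paste0("Design targets not in the network: ", toString(bad)))
  }
  treatments <- design_treatments(design)
  S <- matrix(0, length(node_names), length(treatments),
              dimnames = list(node_names, treatments))
  S[cbind(match(design$target, node_names), match(design$treatment, treatments))] <-
    design$effect
  S
}

#' Steady-state global response of a network to a perturbation design
#'
#' Applies the linearised modular-response-analysis forward model
#' `R = -r^{-1} S`: column k of R is the steady-state log2 response of every
#' node to treatment k, propagating the direct effects S through the network
#' of local response coefficients r.
#'
#' @param truth A `gt_network`.
#' @param design A `perturbation_design` whose targets are nodes of `truth`.
#' @return Numeric matrix, nodes x treatments, of noise-free log2 responses.
#' @examples
#' net <- generate_network(4, 0.3, seed = 2)
#' des <- perturbation_design(
#'   data.frame(treatment = "tx1", target = "N1", effect = 1))
#' simulate_global_response(net, des)
#' @export
simulate_global_response <- function(truth, design) {
  r <- truth$local_response
  if (abs(det(r)) <= 1e-12) abort("Local response matrix is singular.")
  S <- design_matrix(design, truth$node_names)
  R <- -solve(r, S)
  dimnames(R) <- dimnames(S)
  R
}

#' Simulate a replicate-level RPPA dataset from a known network
#'
#' Emits a long-format analyte table emulating an RPPA perturbation
#' experiment: control replicates measure basal levels with Gaussian noise on
#' log2 scale; treated replicates add the network's noise-free global response
#' to the treatment. When a `node_map` with lumped groups is supplied, each
#' node's response is emitted once per analyte (each analyte receives its own
#' replicate noise), mimicking multiple phospho-site antibodies per protein.
#'
#' @param truth A `gt_network`.
#' @param design A `perturbation_design`.
#' @param basal_levels Positive per-node basal levels (arbitrary units);
#'   recycled if length 1.
#' @param node_map Optional tibble (`analyte`, `node`); default one analyte
#'   per node named after it.
#' @param cell_line Cell-line identifier stamped on every row.
#' @param seed RNG seed for the replicate noise; defaults to `truth$seed`.
#' @return A `simulated_dataset`: list with `analyte_table` (tibble:
#'   cell_line, treatment, replicate, analyte, value), `truth`, `design`,
#'   `true_global_response`, `node_map`, `seed`.
#' @export
emit_dataset <- function(truth, design, basal_levels = 1000, node_map = NULL,
                         cell_line = "SYN1", seed = NULL) {
  nodes <- truth$node_names
  if (any(basal_levels <= 0)) abort("`basal_levels` must be positive.")
  basal <- rep_len(basal_levels, length(nodes))
  names(basal) <- nodes
  if (is.null(node_map)) node_map <- tibble(analyte = nodes, node = nodes)
  bad <- setdiff(node_map$node, nodes)
  if (length(bad)) abort(paste0("node_map nodes not in network: ", toString(bad)))
  seed <- as.integer(seed %||% truth$seed)

  R <- simulate_global_response(truth, design)
  treatments <- c("control", colnames(R))
  reps <- design_replicates(design)

  grid <- expand_grid(
    treatment = treatments,
    replicate = seq_len(reps),
    analyte = node_map$analyte
  ) |>
    left_join(node_map, by = "analyte") |>
    mutate(
      delta = ifelse(.data$treatment == "control", 0,
                     R[cbind(.data$node,
                             replace(.data$treatment,
                                     .data$treatment == "control",
                                     colnames(R)[1]))]),
      log2_expected = log2(basal[.data$node]) + .data$delta
    )
  noise <- withr::with_seed(seed, rnorm(nrow(grid), 0, truth$noise_sd))
  tab <- grid |>
    mutate(cell_line = cell_line, value = 2^(.data$log2_expected + noise)) |>
    select("cell_line", "treatment", "replicate", "analyte", "value")

  structure(
    list(analyte_table = tab, truth = truth, design = design,
         true_global_response = R, node_map = node_map, seed = seed),
    class = "simulated_dataset"
  )
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "<simulated_dataset> %s: %d nodes, %d treatments, %d rows (seed %d)\n",
    x$analyte_table$cell_line[1], length(x$truth$node_names),
    ncol(x$true_global_response), nrow(x$analyte_table), x$seed))
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the analyte table as CSV, the ground-truth edge list as TSV, and a
#' YAML scenario file recording the design, basal seed and noise level, so a
#' simulation can be rerun or used as an external oracle.
#'
#' @param dataset A `simulated_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    analyte_table = file.path(dir, "analyte_table.csv"),
    truth_edges = file.path(dir, "truth_edges.tsv"),
    scenario = file.path(dir, "scenario.yaml")
  )
  readr::write_csv(dataset$analyte_table, paths["analyte_table"])
  readr::write_tsv(tidy(dataset$truth), paths["truth_edges"])
  yaml::write_yaml(
    list(
      seed = dataset$seed,
      noise_sd = dataset$truth$noise_sd,
      replicates = design_replicates(dataset$design),
      treatments = as.data.frame(dataset$design)
    ),
    paths["scenario"]
  )
  invisible(paths)
}
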