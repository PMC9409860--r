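#' Canonical prior edges for the TNBC signalling panel
#'
#' The default list of known pathway interactions used to build the prior
#' network: the PI3K-AKT-mTOR-S6 axis, the RAF-MEK-ERK cascade and its
#' feedback into p70S6K, AMPK input to mTOR, PTEN regulation of PI3K, the
#' p53-CHK1 DNA-damage link, and FAK input to PI3K. Shipped as a plain-text
#' table so users can replace it with their own pathway knowledge.
#'
#' @return Tibble with columns `from`, `to`.
#' @export
canonical_edges <- function() {
  path <- system.file("extdata", "canonical_edges.tsv", package = "perturbnet")
  readr::read_tsv(path, col_types = "cc")
}

#' Build a prior network over an ordered node set
#'
#' Encodes pathway knowledge and the perturbation design as per-edge prior
#' inclusion probabilities for Bayesian network inference: canonical
#' interactions get a high prior, edges from every directly perturbed node to
#' every other node a moderate prior, and all remaining edges a low
#' background prior. Two hard structural constraints reflect the tight MAPK
#' cascade: MEK's only admissible parent is RAF, and ERK's only admissible
#' parent is MEK (prior probability 0 for any other incoming edge, applied
#' whenever those nodes are present).
#'
#' @param node_names Ordered node identifiers.
#' @param design Optional `perturbation_design`; its targets define the
#'   perturbed nodes.
#' @param canonical Tibble (`from`, `to`) of canonical edges; default
#'   [canonical_edges()] restricted to `node_names`.
#' @param pi_canonical,pi_perturbed,pi_background Prior inclusion
#'   probabilities for the three edge classes (defaults 0.9 / 0.5 / 0.1).
#' @param constrain_mapk Apply the RAF->MEK->ERK-only constraints when the
#'   nodes exist; default TRUE.
#' @return A `prior_network`: tibble with `from`, `to`, `prior_prob` covering
#'   every ordered off-diagonal pair.
#' @export
prior_network <- function(node_names, design = NULL, canonical = NULL,
                          pi_canonical = 0.9, pi_perturbed = 0.5,
                          pi_background = 0.1, constrain_mapk = TRUE) {
  stopifnot(!anyDuplicated(node_names))
  if (is.null(canonical)) {
    canonical <- canonical_edges() |>
      filter(.data$from %in% node_names, .data$to %in% node_names)
  }
  grid <- expand_grid(from = node_names, to = node_names) |>
    filter(.data$from != .data$to) |>
    mutate(prior_prob = pi_background)
  if (!is.null(design)) {
    perturbed <- intersect(unique(design$target), node_names)
    grid <- grid |>
      mutate(prior_prob = ifelse(.data$from %in% perturbed,
                                 pi_perturbed, .data$prior_prob))
  }
  grid <- grid |>
    left_join(canonical |> mutate(canon = TRUE), by = c("from", "to")) |>
    mutate(prior_prob = ifelse(!is.na(.data$canon), pi_canonical,
                               .data$prior_prob)) |>
    select(-"canon")
  if (constrain_mapk) {
    if ("MEK" %in% node_names) {
      grid <- grid |>
        mutate(prior_prob = ifelse(.data$to == "MEK" & .data$from != "RAF",
                                   0, .data$prior_prob))
    }
    if ("ERK" %in% node_names) {
      grid <- grid |>
        mutate(prior_prob = ifelse(.data$to == "ERK" & .data$from != "MEK",
                                   0, .data$prior_prob))
    }
  }
  if (any(grid$prior_prob < 0 | grid$prior_prob > 1)) {
    abort("Prior probabilities must lie in [0, 1].")
  }
  structure(grid, class = c("prior_network", class(grid)))
}

#' Uniform prior over all off-diagonal edges
#'
#' Convenience prior with the same inclusion probability everywhere, used for
#' benchmarking inference without pathway knowledge.
#' @param node_names Ordered node identifiers.
#' @param pi Common prior inclusion probability, default 0.5.
#' @return A `prior_network`.
#' @export
flat_prior <- function(node_names, pi = 0.5) {
  prior_network(node_names, design = NULL,
                canonical = tibble(from = character(), to = character()),
                pi_background = pi, constrain_mapk = FALSE)
}

prior_matrix <- function(prior, node_names) {
  P <- matrix(NA_real_, length(node_names), length(node_names),
              dimnames = list(node_names, node_names))
  bad <- setdiff(unique(c(prior$from, prior$to)), node_names)
  if (length(bad)) abort(paste0("Prior references unknown nodes: ", toString(bad)))
  # P[i, j] = prior probability of edge j -> i (parent in column)
  P[cbind(match(prior$to, node_names), match(prior$from, node_names))] <-
    prior$prior_prob
  diag(P) <- 0
  if (anyNA(P)) abort("Prior must cover every ordered off-diagonal node pair.")
  P
}

#' MCMC configuration for Bayesian modular response analysis
#'
#' @param noit Gibbs iterations per node (default 1000).
#' @param burnin Discarded initial iterations (default 500; must be < noit).
#' @param times Total posterior-sample budget recorded in run metadata; kept
#'   for compatibility with the original tooling's hyperparameter set
#'   (default 10000).
#' @param g Zellner g-prior scale; `NULL` (default) uses the number of
#'   admissible treatment columns for the node being fit. Larger g means a
#'   vaguer coefficient prior and less shrinkage.
#' @param edge_threshold Posterior-probability cutoff defining the inferred
#'   edge set (default 0.5).
#' @param seed Integer RNG seed.
#' @return A `bmra_config` list.
#' @export
bmra_config <- function(noit = 1000L, burnin = 500L, times = 10000L,
                        g = NULL, edge_threshold = 0.5, seed = 1L) {
  if (burnin >= noit) abort("`burnin` must be smaller than `noit`.")
  if (edge_threshold <= 0 || edge_threshold >= 1) {
    abort("`edge_threshold` must be in (0, 1).")
  }
  structure(
    list(noit = as.integer(noit), burnin = as.integer(burnin),
         times = as.integer(times), g = g,
         edge_threshold = edge_threshold, seed = as.integer(seed)),
    class = "bmra_config"
  )
}

#' Set up the per-node MRA regression block
#'
#' Under modular response analysis, the global response of node i to any
#' treatment that does not target i directly is a linear combination of the
#' other nodes' responses: `R[i, k] = sum_j r_ij R[j, k]`. This builds that
#' regression: the response `y` is node i's row of the global response matrix
#' restricted to admissible (non-self-targeting) treatments, and the design
#' `X` holds the other nodes' responses on the same treatments, restricted to
#' candidate parents allowed by the prior.
#'
#' @param R Global response matrix (nodes x treatments, log2 fold changes).
#' @param node Node identifier (a row of `R`).
#' @param design `perturbation_design` giving each treatment's direct targets.
#' @param prior Optional `prior_network`; parents with prior probability 0
#'   are dropped from the candidate set.
#' @return List with `y`, `X` (admissible treatments x candidate parents),
#'   `candidates`, `prior_prob` (per candidate), `admissible` treatments.
#' @export
build_node_regression <- function(R, node, design, prior = NULL) {
  if (!node %in% rownames(R)) abort(paste0("Unknown node: ", node))
  targets <- design |>
    filter(.data$target == node) |>
    pull("treatment")
  admissible <- setdiff(colnames(R), targets)
  if (!length(admissible)) {
    abort(paste0("Node ", node, " has no admissible treatment columns: ",
                 "every treatment targets it directly."))
  }
  others <- setdiff(rownames(R), node)
  pi <- rep(0.5, length(others))
  names(pi) <- others
  if (!is.null(prior)) {
    P <- prior_matrix(prior, rownames(R))
    pi <- setNames(P[node, others], others)
  }
  candidates <- others[pi > 0]
  list(
    node = node,
    y = R[node, admissible],
    X = t(R[candidates, admissible, drop = FALSE]),
    candidates = candidates,
    prior_prob = pi[candidates],
    admissible = admissible
  )
}

#' Gibbs-sample the parent set of one node
#'
#' Spike-and-slab variable selection on the node's MRA regression. Given an
#' inclusion indicator vector, coefficients are integrated out analytically
#' under a Zellner g-prior with a Jeffreys-type prior on the noise variance,
#' giving a closed-form marginal likelihood; a single-flip Gibbs sweep over
#' the free indicators combines that marginal likelihood with the Bernoulli
#' prior on each edge. Edges with prior probability 1 are always included,
#' edges with prior 0 never enter the candidate set.
#'
#' @param block Output of [build_node_regression()].
#' @param config A [bmra_config()].
#' @param seed RNG seed for this node's chain; default `config$seed`.
#' @return List with `posterior_prob` (named per candidate), `coef`
#'   (posterior mean local response coefficient conditional on inclusion;
#'   NA if never included), `n_samples`, `ridge_used`.
#' @export
sample_topology <- function(block, config = bmra_config(), seed = config$seed) {
  y <- as.numeric(block$y)
  X <- block$X
  pi <- block$prior_prob
  p <- length(block$candidates)
  K <- length(y)
  g <- config$g %||% K
  if (p == 0) {
    return(list(posterior_prob = setNames(numeric(0), character(0)),
                coef = setNames(numeric(0), character(0)),
                n_samples = 0L, ridge_used = FALSE))
  }

  XtX <- crossprod(X)
  Xty <- crossprod(X, y)[, 1]
  yty <- sum(y^2)
  ridge_used <- FALSE

  # Marginal log-likelihood of the model with indicator set `act` (logical p),
  # up to an additive constant shared by all models for this node.
  fit_quad <- function(act, g_cur = g) {
    if (!any(act)) return(list(q = 0, bmean = NULL))
    M <- XtX[act, act, drop = FALSE]
    b <- Xty[act]
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) {
      ridge_used <<- TRUE
      ch <- chol(M + diag(1e-8, nrow(M)))
    }
    u <- backsolve(ch, forwardsolve(t(ch), b))
    list(q = sum(b * u), bmean = g_cur / (1 + g_cur) * u)
  }
  logml <- function(act, g_cur = g) {
    fq <- fit_quad(act, g_cur)
    s <- max(yty - g_cur / (1 + g_cur) * fq$q, 1e-12)
    -sum(act) / 2 * log1p(g_cur) - K / 2 * log(s)
  }

  hard_in <- pi >= 1
  free <- which(!hard_in)
  log_odds_prior <- log(pmin(pi, 1 - 1e-12)) - log(pmax(1 - pi, 1e-12))

  n_keep <- config$noit - config$burnin
  prob_sum <- numeric(p)
  prob_sum[hard_in] <- n_keep  # hard inclusions never leave the model
  coef_sum <- numeric(p)
  coef_n <- integer(p)

  # Burn-in anneals the g-prior scale from a permissive value up to its
  # target on a log ramp. Small g means weak complexity penalties, letting
  # the chain assemble multi-parent models one edge at a time; the target g
  # then resolves near-substitute models sharply. A fixed vague g alone
  # traps the single-flip chain: the first parent of a multi-parent node
  # rarely pays for its own Occam factor.
  g_min <- min(g, 10)
  g_ramp <- if (config$burnin > 0) {
    exp(seq(log(g_min), log(g), length.out = config$burnin))
  } else {
    numeric(0)
  }

  withr::with_seed(seed, {
    act <- hard_in
    for (it in seq_len(config$noit)) {
      keep <- it > config$burnin
      g_it <- if (keep) g else g_ramp[it]
      for (j in free) {
        a1 <- act; a1[j] <- TRUE
        a0 <- act; a0[j] <- FALSE
        d <- (logml(a1, g_it) + log_odds_prior[j]) - logml(a0, g_it)
        p1 <- 1 / (1 + exp(-d))
        act[j] <- runif(1) < p1
        # Rao-Blackwellised inclusion probability: average the full
        # conditional rather than the binary draw (lower MC variance).
        if (keep) prob_sum[j] <- prob_sum[j] + p1
      }
      if (keep && any(act)) {
        bm <- fit_quad(act)$bmean
        coef_sum[act] <- coef_sum[act] + bm
        coef_n[act] <- coef_n[act] + 1L
      }
    }
  })

  post <- prob_sum / n_keep
  cf <- ifelse(coef_n > 0, coef_sum / pmax(coef_n, 1L), NA_real_)
  if (ridge_used) {
    warn(paste0("Singular candidate cross-product for node ", block$node,
                "; ridge jitter 1e-8 applied."))
  }
  list(
    posterior_prob = setNames(post, block$candidates),
    coef = setNames(cf, block$candidates),
    n_samples = n_keep,
    ridge_used = ridge_used
  )
}

#' Infer a signalling network by Bayesian modular response analysis
#'
#' Runs [sample_topology()] for every node of a global response matrix and
#' assembles posterior edge probabilities and posterior mean local response
#' coefficients into a network fit. A node for which every treatment is a
#' direct target (no admissible regression columns) is skipped with a
#' warning; its incoming edges are reported as NA.
#'
#' @param R Global response matrix (nodes x treatments), e.g. from
#'   [response_matrix()], or a `fold_change_tbl` for a single cell line.
#' @param design `perturbation_design` mapping treatments to direct targets.
#' @param prior A `prior_network`; default [prior_network()] over the matrix
#'   nodes with the design's perturbed-node edges.
#' @param config A [bmra_config()].
#' @param cell_line Label stored on the fit.
#' @return A `bmra_fit`: list with `posterior_prob` and `strength` matrices
#'   (entry \[i, j\] refers to the edge j -> i), `edges` tibble, `nodes`,
#'   `config`, `cell_line`, `skipped` nodes.
#' @examples
#' \donttest{
#' net <- generate_network(5, 0.3, seed = 3, noise_sd = 0)
#' des <- perturbation_design(
#'   data.frame(treatment = paste0("tx", 1:5),
#'              target = net$node_names, effect = -1))
#' R <- simulate_global_response(net, des)
#' fit <- infer_network(R, des, prior = flat_prior(net$node_names),
#'                      config = bmra_config(noit = 300, burnin = 100))
#' tidy(fit)
#' }
#' @export
infer_network <- function(R, design, prior = NULL, config = bmra_config(),
                          cell_line = "unspecified") {
  if (inherits(R, "fold_change_tbl")) {
    if (length(unique(R$cell_line)) == 1) cell_line <- unique(R$cell_line)
    R <- response_matrix(R)
  }
  nodes <- rownames(R)
  if (is.null(prior)) prior <- prior_network(nodes, design = design)
  Ppri <- prior_matrix(prior, nodes)

  n <- length(nodes)
  post <- matrix(0, n, n, dimnames = list(nodes, nodes))
  strength <- matrix(0, n, n, dimnames = list(nodes, nodes))
  skipped <- character(0)

  for (i in seq_along(nodes)) {
    node <- nodes[i]
    block <- tryCatch(
      build_node_regression(R, node, design, prior),
      error = function(e) e
    )
    if (inherits(block, "error")) {
      warn(paste0("Skipping node ", node, ": ", conditionMessage(block)))
      post[i, ] <- NA_real_
      strength[i, ] <- NA_real_
      skipped <- c(skipped, node)
      next
    }
    res <- sample_topology(block, config, seed = config$seed + i)
    post[node, block$candidates] <- res$posterior_prob
    strength[node, block$candidates] <- ifelse(is.na(res$coef), 0, res$coef)
  }
  diag(post) <- NA_real_
  diag(strength) <- NA_real_

  edges <- expand_grid(to = nodes, from = nodes) |>
    filter(.data$from != .data$to) |>
    mutate(
      posterior_prob = post[cbind(.data$to, .data$from)],
      strength = strength[cbind(.data$to, .data$from)],
      prior_prob = Ppri[cbind(.data$to, .data$from)],
      included = !is.na(.data$posterior_prob) &
        .data$posterior_prob > config$edge_threshold
    ) |>
    select("from", "to", "posterior_prob", "strength", "prior_prob",
           "included") |>
    arrange(desc(.data$posterior_prob))

  structure(
    list(posterior_prob = post, strength = strength, edges = edges,
         nodes = nodes, config = config, cell_line = cell_line,
         skipped = skipped),
    class = "bmra_fit"
  )
}

#' @export
print.bmra_fit <- function(x, ...) {
  cat(sprintf("<bmra_fit> %s: %d nodes, %d edges at threshold %g (seed %d)\n",
              x$cell_line, length(x$nodes), sum(x$edges$included),
              x$config$edge_threshold, x$config$seed))
  if (length(x$skipped)) cat("  skipped nodes:", toString(x$skipped), "\n")
  invisible(x)
}

#' Tidy a BMRA fit into an edge table
#' @param x A `bmra_fit`.
#' @param ... Unused.
#' @return Tibble with `from`, `to`, `posterior_prob`, `strength`,
#'   `prior_prob`, `included` for every candidate edge.
#' @export
tidy.bmra_fit <- function(x, ...) x$edges

#' One-row summary of a BMRA fit
#' @param x A `bmra_fit`.
#' @param ... Unused.
#' @return Tibble with `cell_line`, `n_nodes`, `n_edges`, `edge_threshold`,
#'   `noit`, `burnin`, `seed`.
#' @export
glance.bmra_fit <- function(x, ...) {
  tibble(
    cell_line = x$cell_line,
    n_nodes = length(x$nodes),
    n_edges = sum(x$edges$included, na.rm = TRUE),
    edge_threshold = x$config$edge_threshold,
    noit = x$config$noit,
    burnin = x$config$burnin,
    seed = x$config$seed
  )
}

#' Exact modular-response-analysis inversion
#'
#' When every node has been perturbed one-by-one (one treatment per node,
#' each targeting exactly that node), the local response matrix follows
#' directly from the global response matrix by `r = -S R^{-1}`, row-rescaled
#' to the convention diag(r) = -1. Exact in the noise-free case; used as the
#' algebraic oracle for the Bayesian sampler.
#'
#' @param R Square global response matrix (nodes x treatments, treatment k
#'   targeting node k).
#' @param S Diagonal matrix (or vector) of direct effects; default identity.
#' @return Local response matrix with diagonal -1.
#' @export
exact_mra_solve <- function(R, S = NULL) {
  if (nrow(R) != ncol(R)) abort("Exact MRA needs a square response matrix.")
  if (abs(det(R)) <= .Machine$double.eps * nrow(R)) {
    abort("Global response matrix is singular.")
  }
  n <- nrow(R)
  if (is.null(S)) S <- diag(n)
  if (is.vector(S)) S <- diag(S, n)
  r <- -S %*% solve(R)
  r <- r / (-diag(r))  # row-rescale so the self-effect is -1
  dimnames(r) <- list(rownames(R), rownames(R))
  r
}

#' Export an inferred network to GraphML
#'
#' Writes the thresholded edge set with `posterior_prob` and `strength` edge
#' attributes, readable by Cytoscape and igraph.
#' @param fit A `bmra_fit`.
#' @param path Output file path.
#' @param all_edges Write every candidate edge rather than only included
#'   ones; default FALSE.
#' @return Invisibly, `path`.
#' @export
export_graphml <- function(fit, path, all_edges = FALSE) {
  ed <- tidy(fit)
  if (!all_edges) ed <- ed |> filter(.data$included)
  gr <- igraph::graph_from_data_frame(
    ed |> select("from", "to", "posterior_prob", "strength"),
    directed = TRUE,
    vertices = data.frame(name = fit$nodes)
  )
  igraph::write_graph(gr, path, format = "graphml")
  invisible(path)
}

#' Posterior edge-probability heat map
#' @param object A `bmra_fit`.
#' @param ... Unused.
#' @return A ggplot object: parents on the x axis, child nodes on the y axis,
#'   fill = posterior inclusion probability.
#' @export
autoplot.bmra_fit <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$from, y = .data$to,
                                 fill = .data$posterior_prob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b",
                                 limits = c(0, 1), name = "P(edge)") +
    ggplot2::labs(x = "parent (source)", y = "child (target)",
                  title = paste("Posterior edge probabilities:",
                                object$cell_line)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
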