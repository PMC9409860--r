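#' Simulate a two-group perturbation study
#'
#' Emulates the structure of a sensitive-versus-resistant cell-line panel:
#' each group has its own ground-truth network (so group networks genuinely
#' differ), every member cell line shares its group's truth but receives an
#' independent replicate-noise realisation, and the resistant group's basal
#' levels are shifted upward on a configurable set of nodes (by default the
#' PI3K-AKT axis nodes, mimicking constitutive pathway activation).
#'
#' @param n_per_group Cell lines per group (default 3).
#' @param n_nodes Network size (default 18, the panel's node count).
#' @param edge_density Ground-truth edge density (default 0.2).
#' @param strength_range Magnitude range of true local response coefficients.
#' @param noise_sd Replicate noise SD on log2 scale (default 0.05).
#' @param design Perturbation design; default [tnbc_design()] for 18-node
#'   networks, else one inhibitory treatment per node for the first
#'   `min(n_nodes, 12)` nodes.
#' @param basal_shift_nodes Nodes with elevated basal level in the resistant
#'   group (default PI3K, PDK1, AKT when present).
#' @param basal_shift Log2 shift applied to those nodes (default 1).
#' @param seed Integer seed; group truths and member noise derive from it.
#' @return List with `analyte_table` (all cell lines), `groups` tibble,
#'   `truths` (per group `gt_network`), `design`, `datasets` (per cell line
#'   `simulated_dataset`), `seed`.
#' @export
simulate_study <- function(n_per_group = 3, n_nodes = 18, edge_density = 0.2,
                           strength_range = c(0.3, 1), noise_sd = 0.05,
                           design = NULL,
                           basal_shift_nodes = c("PI3K", "PDK1", "AKT"),
                           basal_shift = 1, seed = 1L) {
  seed <- as.integer(seed)
  truths <- list(
    sensitive = generate_network(n_nodes, edge_density, strength_range,
                                 noise_sd = noise_sd, seed = seed),
    resistant = generate_network(n_nodes, edge_density, strength_range,
                                 noise_sd = noise_sd, seed = seed + 1L)
  )
  nodes <- truths$sensitive$node_names
  if (is.null(design)) {
    design <- if (n_nodes == 18) {
      tnbc_design()
    } else {
      k <- min(n_nodes, 12L)
      perturbation_design(tibble(treatment = paste0("tx", seq_len(k)),
                                 target = nodes[seq_len(k)], effect = -1))
    }
  }
  node_map <- if (n_nodes == 18) tnbc_node_map() else NULL
  basal <- setNames(rep(1000, n_nodes), nodes)
  basal_res <- basal
  shift_nodes <- intersect(basal_shift_nodes, nodes)
  basal_res[shift_nodes] <- basal_res[shift_nodes] * 2^basal_shift

  groups <- expand_grid(group = c("sensitive", "resistant"),
                        member = seq_len(n_per_group)) |>
    mutate(cell_line = sprintf("%s_%d", toupper(substr(.data$group, 1, 3)),
                               .data$member)) |>
    select("cell_line", "group")

  datasets <- purrr::pmap(groups, function(cell_line, group) {
    i <- which(groups$cell_line == cell_line)
    emit_dataset(
      truths[[group]], design,
      basal_levels = if (group == "resistant") basal_res else basal,
      node_map = node_map, cell_line = cell_line,
      seed = seed + 100L * i
    )
  })
  names(datasets) <- groups$cell_line

  list(
    analyte_table = list_rbind(map(datasets, "analyte_table")),
    groups = groups,
    truths = truths,
    design = design,
    datasets = datasets,
    seed = seed
  )
}

#' Read and validate a pipeline run configuration
#'
#' Accepts a YAML file path or a list. Checks that every referenced file
#' exists before any computation starts.
#'
#' @param config YAML path or list. Recognised keys: `analyte_table` (CSV
#'   path or data frame) or `simulate` (argument list for
#'   [simulate_study()]); `groups` (named list `group -> cell lines`, data
#'   frame, or CSV path); `node_map`, `prior` (optional file paths or data
#'   frames); `alpha`; `strong_threshold`; `bmra` (arguments for
#'   [bmra_config()]); `seed`; `out_dir`.
#' @return Validated config list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(alpha = 0.05, strong_threshold = 0.4, seed = 1L,
                   bmra = list(), out_dir = NULL)
  config <- modifyList(defaults, config)
  if (is.null(config$analyte_table) && is.null(config$simulate)) {
    abort("Config must provide either `analyte_table` or `simulate`.")
  }
  for (key in c("analyte_table", "node_map", "prior", "groups")) {
    val <- config[[key]]
    if (is.character(val) && length(val) == 1 && !file.exists(val)) {
      abort(paste0("Configured ", key, " file not found: ", val),
            class = "perturbnet_config_error")
    }
  }
  if (is.null(config$out_dir)) abort("Config must set `out_dir`.")
  structure(config, class = c("run_config", "list"))
}

read_table_arg <- function(x, reader = readr::read_csv) {
  if (is.character(x) && length(x) == 1) {
    reader(x, show_col_types = FALSE)
  } else {
    as_tibble(x)
  }
}

normalise_groups <- function(groups) {
  if (is.null(groups)) return(NULL)
  if (is.character(groups) && length(groups) == 1) {
    return(readr::read_csv(groups, col_types = "cc"))
  }
  if (is.data.frame(groups)) return(as_tibble(groups))
  # named list: group -> member cell lines
  imap(groups, function(members, g) tibble(cell_line = members, group = g)) |>
    list_rbind()
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", stage, "' failed: ", conditionMessage(e)),
          class = paste0("perturbnet_stage_", stage))
  })
}

#' Run the full perturbation-analysis pipeline
#'
#' Executes, in order: log2 fold-change computation, analyte-to-node lumping,
#' per-cell-line Bayesian network inference, group consensus networks,
#' differential edge testing, and basal activity comparison. Every stage's
#' output is written as plain text under `out_dir`, and a `manifest.json`
#' records the config, its hash, the seed, package version, and per-stage
#' files, so a rerun with the same config and seed is bit-identical.
#'
#' @param config A [read_run_config()] input (path or list).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "networks"), showWarnings = FALSE)
  seed <- as.integer(config$seed)
  outputs <- list()

  if (!is.null(config$simulate)) {
    sim_args <- modifyList(list(seed = seed), as.list(config$simulate))
    study <- do.call(simulate_study, sim_args)
    analyte_table <- study$analyte_table
    groups <- study$groups
    design <- study$design
  } else {
    analyte_table <- read_table_arg(config$analyte_table)
    groups <- normalise_groups(config$groups)
    design <- config$design %||% tnbc_design()
    if (is.character(design)) {
      design <- perturbation_design(readr::read_csv(design, show_col_types = FALSE))
    }
  }
  if (is.null(groups)) abort("Config must define `groups` (or use `simulate`).")

  node_map <- config$node_map
  if (is.null(node_map)) {
    analytes <- unique(analyte_table$analyte)
    node_map <- if (all(analytes %in% tnbc_node_map()$analyte)) {
      tnbc_node_map()
    } else {
      tibble(analyte = analytes, node = analytes)
    }
  } else {
    node_map <- read_table_arg(node_map)
  }

  # Stage 1-2: fold changes, lumping
  fc_raw <- run_stage("fold_change",
                      compute_log2_foldchanges(analyte_table, alpha = config$alpha))
  fc <- run_stage("lump_nodes", lump_nodes(fc_raw, node_map))
  outputs$fold_changes <- file.path(out_dir, "fold_changes.csv")
  readr::write_csv(fc_raw, outputs$fold_changes)
  outputs$fold_changes_lumped <- file.path(out_dir, "fold_changes_lumped.csv")
  readr::write_csv(fc, outputs$fold_changes_lumped)

  # Stage 3: per-cell-line network inference
  nodes <- sort(unique(fc$node))
  prior <- if (is.null(config$prior)) {
    prior_network(nodes, design = design)
  } else {
    pr <- read_table_arg(config$prior, reader = readr::read_tsv)
    structure(pr, class = c("prior_network", class(pr)))
  }
  bmra_args <- modifyList(list(seed = seed + 1000L), as.list(config$bmra))
  cfg <- do.call(bmra_config, bmra_args)
  cell_lines <- intersect(unique(fc$cell_line), groups$cell_line)
  fits <- run_stage("bmra", {
    res <- map(seq_along(cell_lines), function(i) {
      cl <- cell_lines[i]
      cfg_i <- cfg
      cfg_i$seed <- cfg$seed + 1000L * i
      infer_network(response_matrix(fc, cell_line = cl), design,
                    prior = prior, config = cfg_i, cell_line = cl)
    })
    names(res) <- cell_lines
    res
  })
  for (cl in cell_lines) {
    path <- file.path(out_dir, "networks", paste0(cl, "_edges.tsv"))
    readr::write_tsv(tidy(fits[[cl]]), path)
    outputs[[paste0("network_", cl)]] <- path
  }
  outputs$network_summary <- file.path(out_dir, "network_summary.csv")
  readr::write_csv(list_rbind(map(fits, glance)), outputs$network_summary)

  # Stage 4: group consensus networks
  by_group <- split(groups$cell_line, groups$group)
  consensus <- run_stage("consensus", imap(by_group, function(members, g) {
    consensus_network(fits[intersect(members, cell_lines)],
                      strong_threshold = config$strong_threshold, group = g)
  }))
  for (g in names(consensus)) {
    path <- file.path(out_dir, paste0("consensus_", g, ".tsv"))
    readr::write_tsv(consensus[[g]], path)
    outputs[[paste0("consensus_", g)]] <- path
  }

  # Stage 5: differential edges (needs >= 2 members per group)
  differential <- NULL
  if (all(lengths(by_group) >= 2) && length(by_group) == 2) {
    gs <- names(by_group)
    ref <- if ("sensitive" %in% gs) "sensitive" else gs[1]
    other <- setdiff(gs, ref)
    differential <- run_stage("differential",
      differential_edges(fits[intersect(by_group[[ref]], cell_lines)],
                         fits[intersect(by_group[[other]], cell_lines)],
                         alpha = config$alpha))
    outputs$differential_edges <- file.path(out_dir, "differential_edges.csv")
    readr::write_csv(differential, outputs$differential_edges)
  }

  # Stage 6: basal activity comparison
  basal <- run_stage("basal",
                     basal_comparison(analyte_table, groups, node_map = node_map))
  outputs$basal_comparison <- file.path(out_dir, "basal_comparison.csv")
  readr::write_csv(basal, outputs$basal_comparison)

  manifest <- list(
    package_version = as.character(utils::packageVersion("perturbnet")),
    seed = seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    alpha = config$alpha,
    strong_threshold = config$strong_threshold,
    bmra = cfg[c("noit", "burnin", "times", "edge_threshold")],
    cell_lines = cell_lines,
    groups = split(groups$cell_line, groups$group),
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(manifest, list(
    fits = fits, fold_changes = fc, consensus = consensus,
    differential = differential, basal = basal
  )))
}
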