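# Normalise a network (bmra_fit or plain edge table) to (from, to, strength)
# for its included edges. A plain data frame is taken at face value: every row
# with nonzero strength is an edge.
as_edge_strengths <- function(x) {
  if (inherits(x, "bmra_fit")) {
    tidy(x) |>
      filter(.data$included) |>
      select("from", "to", "strength")
  } else {
    x <- as_tibble(x)
    stopifnot(all(c("from", "to", "strength") %in% names(x)))
    x |>
      filter(.data$strength != 0) |>
      select("from", "to", "strength")
  }
}

network_nodes <- function(x) {
  if (inherits(x, "bmra_fit")) x$nodes else sort(unique(c(x$from, x$to)))
}

#' Build a group consensus network
#'
#' Retains an edge only if it is present with the same sign in every member
#' network of the group, and averages the member strengths. Edges whose mean
#' absolute strength exceeds `strong_threshold` (strictly) are flagged as
#' strong interactions.
#'
#' @param networks List of `bmra_fit` objects (or edge tables with `from`,
#'   `to`, `strength`) from the member cell lines.
#' @param strong_threshold Magnitude above which an edge is flagged strong;
#'   default 0.4.
#' @param group Group label stored on the result.
#' @return A `consensus_network` tibble: `from`, `to`, `mean_strength`,
#'   `strong`, `n_members`.
#' @export
consensus_network <- function(networks, strong_threshold = 0.4,
                              group = "group") {
  if (!length(networks)) abort("Need at least one member network.")
  if (inherits(networks, "bmra_fit")) networks <- list(networks)
  # node sets are only well defined for full fits; plain edge tables list
  # present edges only and are compared on edges alone
  fits <- purrr::keep(networks, inherits, "bmra_fit")
  if (length(fits) > 1) {
    ref <- sort(fits[[1]]$nodes)
    same <- map_lgl(fits[-1], function(f) identical(sort(f$nodes), ref))
    if (!all(same)) abort("Member networks have mismatched node sets.")
  }
  members <- imap(networks, function(x, i) {
    as_edge_strengths(x) |> mutate(member = i)
  }) |>
    list_rbind()
  k <- length(networks)
  out <- members |>
    summarise(
      n_present = n(),
      sign_consistent = all(sign(.data$strength) == sign(.data$strength[1])),
      mean_strength = mean(.data$strength),
      .by = c("from", "to")
    ) |>
    filter(.data$n_present == k, .data$sign_consistent) |>
    transmute(
      .data$from, .data$to, .data$mean_strength,
      strong = abs(.data$mean_strength) > strong_threshold,
      n_members = k
    ) |>
    arrange(desc(abs(.data$mean_strength)))
  structure(out, group = group, strong_threshold = strong_threshold,
            class = c("consensus_network", class(out)))
}

# Per-edge member strengths over the union of candidate edges, absent edges
# contributing strength 0 (absence is treated as evidence of no interaction).
edge_strength_matrix <- function(networks) {
  tabs <- map(networks, as_edge_strengths)
  all_edges <- list_rbind(tabs) |> distinct(.data$from, .data$to)
  map(tabs, function(tb) {
    all_edges |>
      left_join(tb, by = c("from", "to")) |>
      mutate(strength = replace_na(.data$strength, 0)) |>
      pull("strength")
  }) |>
    do.call(what = cbind) |>
    (\(m) list(edges = all_edges, strengths = m))()
}

# Two-sample t statistic and p-value (x vs y), tolerating zero variance.
two_sample_t <- function(x, y, var_equal = TRUE) {
  if (sd(x) == 0 && sd(y) == 0) {
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (equal) 0 else Inf * sign(mean(x) - mean(y)),
                p = if (equal) 1 else 0))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value)
}

classify_rewiring <- function(ms, mr, tol = 1e-12) {
  s <- ifelse(abs(ms) < tol, 0, sign(ms))
  r <- ifelse(abs(mr) < tol, 0, sign(mr))
  dplyr::case_when(
    s > 0 & r < 0 ~ "activation_to_inhibition",
    s < 0 & r > 0 ~ "inhibition_to_activation",
    s == 0 & r > 0 ~ "gain_of_activation",
    s == 0 & r < 0 ~ "gain_of_inhibition",
    s != 0 & r == 0 ~ "loss_of_interaction",
    s == 0 & r == 0 ~ "absent",
    TRUE ~ "magnitude_change"
  )
}

#' Test edges for sensitive-versus-resistant differences
#'
#' For every candidate edge (the union over both groups' inferred edges),
#' compares the member strengths between groups with a two-sample t-test,
#' an absent edge contributing strength 0. The default is the equal-variance
#' Student test; set `var_equal = FALSE` for Welch. The t statistic is
#' oriented resistant minus sensitive.
#'
#' @param sensitive,resistant Lists (>= 2 each) of `bmra_fit` objects or edge
#'   tables for the two groups.
#' @param alpha Significance level for the flag, default 0.05 (no
#'   multiple-testing correction, matching the raw-p reporting convention
#'   for this analysis).
#' @param var_equal Use the pooled-variance Student test (default TRUE).
#' @return Tibble ranked by p-value: `from`, `to`, `mean_sensitive`,
#'   `mean_resistant`, `t`, `p_value`, `significant`, `rewiring`.
#' @export
differential_edges <- function(sensitive, resistant, alpha = 0.05,
                               var_equal = TRUE) {
  if (length(sensitive) < 2 || length(resistant) < 2) {
    abort("Each group needs at least 2 member networks for a two-sample test.")
  }
  em <- edge_strength_matrix(c(sensitive, resistant))
  idx_s <- seq_along(sensitive)
  idx_r <- length(sensitive) + seq_along(resistant)
  tests <- map(seq_len(nrow(em$edges)), function(e) {
    s <- em$strengths[e, idx_s]
    r <- em$strengths[e, idx_r]
    tt <- two_sample_t(r, s, var_equal = var_equal)
    tibble(mean_sensitive = mean(s), mean_resistant = mean(r),
           t = tt$t, p_value = tt$p)
  }) |>
    list_rbind()
  bind_cols(em$edges, tests) |>
    mutate(
      significant = .data$p_value < alpha,
      rewiring = classify_rewiring(.data$mean_sensitive, .data$mean_resistant)
    ) |>
    arrange(.data$p_value, desc(abs(.data$t)))
}

#' Compare basal (unperturbed) activity between groups
#'
#' Uses only the control condition: per cell line and analyte, the mean log2
#' basal level over replicates, lumped to network nodes, then per node a
#' Welch two-sample t-test between the two groups of cell lines. The signed
#' difference is oriented resistant minus sensitive (more generally,
#' non-reference minus reference group).
#'
#' @param table Replicate-level analyte table (see
#'   [compute_log2_foldchanges()]).
#' @param groups Data frame with columns `cell_line`, `group` (exactly two
#'   group labels), or a named character vector `cell_line -> group`.
#' @param node_map Analyte-to-node map; default [tnbc_node_map()] when its
#'   analytes cover the table, else identity.
#' @param reference Reference group label; default `"sensitive"` when
#'   present, else the first label alphabetically.
#' @return Tibble per node: group means, `difference`, `t`, `p_value`,
#'   ranked by p-value.
#' @export
basal_comparison <- function(table, groups, node_map = NULL,
                             reference = NULL) {
  if (!is.data.frame(groups)) {
    groups <- tibble(cell_line = names(groups), group = unname(groups))
  }
  groups <- as_tibble(groups)
  lv <- sort(unique(groups$group))
  if (length(lv) != 2) abort("`groups` must define exactly two groups.")
  counts <- vapply(lv, function(g) sum(groups$group == g), integer(1))
  if (any(counts == 0)) {
    abort(paste0("Group with no members: ", lv[counts == 0][1]))
  }
  reference <- reference %||% (if ("sensitive" %in% lv) "sensitive" else lv[1])
  other <- setdiff(lv, reference)

  tab <- as_tibble(table) |> filter(.data$treatment == "control")
  missing_ctrl <- setdiff(groups$cell_line, unique(tab$cell_line))
  if (length(missing_ctrl)) {
    abort(paste0("No untreated condition for cell line(s): ",
                 toString(missing_ctrl)))
  }
  if (is.null(node_map)) {
    analytes <- unique(tab$analyte)
    node_map <- if (all(analytes %in% tnbc_node_map()$analyte)) {
      tnbc_node_map()
    } else {
      tibble(analyte = analytes, node = analytes)
    }
  }

  basal <- tab |>
    inner_join(groups, by = "cell_line") |>
    inner_join(node_map, by = "analyte") |>
    summarise(level = mean(log2(.data$value)),
              .by = c("cell_line", "group", "node", "analyte")) |>
    summarise(level = mean(.data$level),
              .by = c("cell_line", "group", "node"))

  basal |>
    summarise(
      res = list(two_sample_t(.data$level[.data$group == other],
                              .data$level[.data$group == reference],
                              var_equal = FALSE)),
      !!paste0("mean_", reference) := mean(.data$level[.data$group == reference]),
      !!paste0("mean_", other) := mean(.data$level[.data$group == other]),
      .by = "node"
    ) |>
    mutate(
      difference = .data[[paste0("mean_", other)]] -
        .data[[paste0("mean_", reference)]],
      t = map_dbl(.data$res, "t"),
      p_value = map_dbl(.data$res, "p")
    ) |>
    select(-"res") |>
    arrange(.data$p_value, desc(abs(.data$difference)))
}
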