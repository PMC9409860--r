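edge_tbl <- function(...) {
  # quick edge-table constructor: edge_tbl("A->B" = 0.5, ...)
  vals <- c(...)
  parts <- strsplit(names(vals), "->", fixed = TRUE)
  tibble::tibble(from = sapply(parts, `[`, 1),
                 to = sapply(parts, `[`, 2),
                 strength = unname(vals))
}

test_that("consensus keeps only sign-consistent edges and averages strengths", {
  # single member: consensus is that network
  single <- consensus_network(list(edge_tbl("A->B" = 0.5, "B->C" = -0.2)))
  expect_equal(nrow(single), 2)
  expect_setequal(single$mean_strength, c(0.5, -0.2))

  # sign-inconsistent edge is dropped
  nets <- list(edge_tbl("A->B" = 0.5), edge_tbl("A->B" = 0.3),
               edge_tbl("A->B" = -0.2))
  expect_equal(nrow(consensus_network(nets)), 0)

  # consistent edge: mean strength, strong threshold strict at 0.4
  nets2 <- list(edge_tbl("A->B" = 0.5), edge_tbl("A->B" = 0.3),
                edge_tbl("A->B" = 0.4))
  cons <- consensus_network(nets2)
  expect_equal(cons$mean_strength, 0.4)
  expect_false(cons$strong)  # |0.4| is not > 0.4
  expect_true(consensus_network(list(edge_tbl("A->B" = 0.41)))$strong)

  # an edge absent from any member is absent from the consensus
  nets3 <- list(edge_tbl("A->B" = 0.5, "B->C" = 0.3), edge_tbl("A->B" = 0.4))
  expect_equal(consensus_network(nets3)$from, "A")
})

test_that("consensus edges are a subset of every member's edges", {
  set.seed(31)
  members <- lapply(1:4, function(i) {
    net <- generate_network(6, 0.4, seed = 30 + i, noise_sd = 0)
    tidy(net) |> dplyr::rename(strength = strength)
  })
  cons <- consensus_network(members)
  for (m in members) {
    expect_true(all(paste(cons$from, cons$to) %in% paste(m$from, m$to)))
  }
})

test_that("consensus rejects mismatched node sets from fits", {
  net4 <- generate_network(4, 0.5, seed = 1, noise_sd = 0)
  net5 <- generate_network(5, 0.5, seed = 2, noise_sd = 0)
  f4 <- infer_network(simulate_global_response(net4, full_design(net4$node_names)),
                      full_design(net4$node_names),
                      prior = flat_prior(net4$node_names), config = quick_cfg())
  f5 <- infer_network(simulate_global_response(net5, full_design(net5$node_names)),
                      full_design(net5$node_names),
                      prior = flat_prior(net5$node_names), config = quick_cfg())
  expect_error(consensus_network(list(f4, f5)), "mismatch")
})

test_that("differential edges rank constructed group differences first", {
  # identical groups: t = 0, p = 1 everywhere
  g <- list(edge_tbl("A->B" = 0.5, "C->D" = -0.3),
            edge_tbl("A->B" = 0.4, "C->D" = -0.2))
  same <- differential_edges(g, g)
  expect_true(all(same$t == 0))
  expect_true(all(same$p_value == 1))

  # one edge flipped from +0.5 to -0.5 across groups (3 vs 3, sd 0.01):
  # it is ranked first with p < 0.05 and annotated as a sign flip
  withr::with_seed(5, {
    sens <- lapply(1:3, function(i)
      edge_tbl("A->B" = 0.5 + rnorm(1, 0, 0.01),
               "C->D" = 0.3 + rnorm(1, 0, 0.01)))
    res <- lapply(1:3, function(i)
      edge_tbl("A->B" = -0.5 + rnorm(1, 0, 0.01),
               "C->D" = 0.3 + rnorm(1, 0, 0.01)))
  })
  de <- differential_edges(sens, res)
  expect_equal(de$from[1], "A")
  expect_lt(de$p_value[1], 0.05)
  expect_equal(de$rewiring[1], "activation_to_inhibition")
  expect_gt(de$p_value[2], 0.05)

  # antisymmetry: swapping groups negates t, preserves p
  de_swap <- differential_edges(res, sens)
  m <- dplyr::inner_join(as.data.frame(de), as.data.frame(de_swap),
                         by = c("from", "to"))
  expect_equal(m$t.x, -m$t.y)
  expect_equal(m$p_value.x, m$p_value.y)

  # group of one is rejected
  expect_error(differential_edges(sens[1], res), "2")
})

test_that("adding a shared member pulls t statistics toward zero", {
  withr::with_seed(9, {
    sens <- lapply(1:3, function(i) edge_tbl("A->B" = 0.5 + rnorm(1, 0, 0.05)))
    res <- lapply(1:3, function(i) edge_tbl("A->B" = -0.5 + rnorm(1, 0, 0.05)))
  })
  shared <- edge_tbl("A->B" = 0)
  t_before <- abs(differential_edges(sens, res)$t[1])
  t_after <- abs(differential_edges(c(sens, list(shared)),
                                    c(res, list(shared)))$t[1])
  expect_lt(t_after, t_before)
})

test_that("basal comparison surfaces constructed group shifts", {
  # two groups sharing a truth, resistant shifted +1 log2 on three nodes
  study <- simulate_study(n_per_group = 3, n_nodes = 8, seed = 17,
                          noise_sd = 0.05,
                          basal_shift_nodes = c("N1", "N2", "N3"),
                          basal_shift = 1)
  # force both groups onto the same network so only basal levels differ
  bc <- basal_comparison(study$analyte_table, study$groups)
  top3 <- bc$node[1:3]
  expect_setequal(top3, c("N1", "N2", "N3"))
  expect_true(all(bc$difference[1:3] > 0.8))
  expect_true(all(abs(bc$difference[4:8]) < 0.2))

  # identical groups: differences near zero
  study0 <- simulate_study(n_per_group = 3, n_nodes = 8, seed = 18,
                           noise_sd = 0.05, basal_shift = 0)
  bc0 <- basal_comparison(study0$analyte_table, study0$groups)
  expect_lt(max(abs(bc0$difference)), 0.15)

  # empty group errors
  expect_error(
    basal_comparison(study$analyte_table,
                     data.frame(cell_line = "SEN_1", group = "sensitive")),
    "two groups")
})
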