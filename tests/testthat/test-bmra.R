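test_that("node regressions expose the MRA linear system", {
  # cascade: R = [[1, 0], [0.5, 1]], treatment k targets node k
  net <- cascade2()
  des <- full_design(net$node_names)
  R <- simulate_global_response(net, des)

  block <- build_node_regression(R, "N2", des)
  expect_equal(block$admissible, "tx_N1")
  expect_equal(unname(block$y), 0.5)
  expect_equal(unname(block$X[, "N1"]), 1)

  # a node targeted by every treatment has no admissible columns
  all_target <- perturbation_design(
    data.frame(treatment = c("tx_N1", "tx_N2"), target = c("N1", "N1"),
               effect = 1))
  expect_error(build_node_regression(R, "N1", all_target), "N1")

  # hard prior exclusions never enter the candidate set
  nodes <- c("RAF", "MEK", "ERK", "AKT")
  net4 <- generate_network(4, 0.5, seed = 6, node_names = nodes)
  des4 <- full_design(nodes)
  R4 <- simulate_global_response(net4, des4)
  pr <- prior_network(nodes, design = des4)
  expect_equal(build_node_regression(R4, "MEK", des4, pr)$candidates, "RAF")
  expect_equal(build_node_regression(R4, "ERK", des4, pr)$candidates, "MEK")
})

test_that("topology sampling concentrates on the true parent as noise vanishes", {
  # three independent perturbations of N1 at different magnitudes make the
  # single-regressor system overdetermined; with near-zero noise the sampler
  # must include N1 -> N2 with certainty and recover the coefficient 0.5
  net <- cascade2()
  net$noise_sd <- 1e-4
  des <- perturbation_design(
    data.frame(treatment = c("a", "b", "c", "d"),
               target = c("N1", "N1", "N1", "N2"),
               effect = c(1, 2, -1, 1)))
  ds <- emit_dataset(net, des, seed = 11)
  R <- response_matrix(compute_log2_foldchanges(ds$analyte_table))
  block <- build_node_regression(R, "N2", des,
                                 flat_prior(c("N1", "N2"), 0.5))
  res <- sample_topology(block, bmra_config(g = 1e6, seed = 3))
  expect_gt(res$posterior_prob[["N1"]], 0.99)
  expect_equal(res$coef[["N1"]], 0.5, tolerance = 1e-2)

  # hard inclusion (pi = 1) never leaves the model
  block_hard <- build_node_regression(R, "N2", des,
                                      flat_prior(c("N1", "N2"), 1 - 1e-9))
  block_hard$prior_prob[] <- 1
  res_hard <- sample_topology(block_hard, quick_cfg())
  expect_equal(unname(res_hard$posterior_prob), 1)
})

test_that("with no signal the sampler never reports confident edges", {
  set.seed(8)
  K <- 10
  block <- list(node = "N0",
                y = rnorm(K, 0, 1e-3),
                X = matrix(rnorm(K * 3), K, 3,
                           dimnames = list(NULL, c("P1", "P2", "P3"))),
                candidates = c("P1", "P2", "P3"),
                prior_prob = c(P1 = 0.5, P2 = 0.5, P3 = 0.5),
                admissible = paste0("t", 1:K))
  res <- sample_topology(block, bmra_config(seed = 4))
  # the flat likelihood leaves only the prior and the Occam factor, which
  # can only shrink inclusion below the prior
  expect_true(all(res$posterior_prob < 0.5))
  expect_true(all(res$posterior_prob > 0.01))
})

test_that("raising an edge's prior never lowers its posterior on average", {
  net <- generate_network(4, 0.5, seed = 12, noise_sd = 0.1)
  des <- full_design(net$node_names)
  ds <- emit_dataset(net, des, seed = 13)
  R <- response_matrix(compute_log2_foldchanges(ds$analyte_table))
  p_at <- function(pi, seeds) {
    mean(sapply(seeds, function(s) {
      block <- build_node_regression(R, "N2", des,
                                     flat_prior(net$node_names, pi))
      sample_topology(block, quick_cfg(seed = s))$posterior_prob[["N1"]]
    }))
  }
  expect_gte(p_at(0.7, 1:8), p_at(0.2, 1:8))
})

test_that("exact MRA inversion is the algebraic oracle it claims to be", {
  # identity responses: no edges
  R <- diag(3)
  dimnames(R) <- list(paste0("N", 1:3), paste0("N", 1:3))
  expect_equal(exact_mra_solve(R), -R)

  # cascade: recover r21 = 0.5, r12 = 0
  net <- cascade2()
  des <- full_design(net$node_names)
  R2 <- simulate_global_response(net, des)
  r <- exact_mra_solve(R2, diag(2))
  expect_equal(unname(r[2, 1]), 0.5)
  expect_equal(unname(r[1, 2]), 0)

  # round trip at n = 18
  net18 <- generate_network(18, 0.2, seed = 21, noise_sd = 0)
  R18 <- simulate_global_response(net18, full_design(net18$node_names))
  expect_lt(max(abs(exact_mra_solve(R18) - net18$local_response)), 1e-9)

  expect_error(exact_mra_solve(matrix(1, 2, 2)), "singular|Singular")
  expect_error(exact_mra_solve(matrix(1, 2, 3)), "square")
})

test_that("network inference recovers noise-free synthetic truth and is reproducible", {
  net <- generate_network(6, 0.3, seed = 4, noise_sd = 0)
  des <- full_design(net$node_names)
  R <- simulate_global_response(net, des)
  cfg <- bmra_config(noit = 400, burnin = 150, g = 1e6, seed = 7)
  fit <- infer_network(R, des, prior = flat_prior(net$node_names), config = cfg)

  truth_edges <- tidy(net)
  found <- tidy(fit) |> dplyr::filter(included)
  expect_setequal(paste(found$from, found$to),
                  paste(truth_edges$from, truth_edges$to))

  # posterior mean strengths agree with the ground truth
  m <- dplyr::inner_join(found, truth_edges, by = c("from", "to"))
  expect_lt(max(abs(m$strength.x - m$strength.y)), 1e-2)

  # identical seed and config: identical fit
  fit2 <- infer_network(R, des, prior = flat_prior(net$node_names),
                        config = cfg)
  expect_equal(fit$posterior_prob, fit2$posterior_prob)
  expect_equal(fit$strength, fit2$strength)

  # hard prior exclusions are respected: inferred edges stay inside support
  pr0 <- support_prior(net, des)
  fit3 <- infer_network(R, des, prior = pr0, config = cfg)
  inferred <- tidy(fit3) |> dplyr::filter(included)
  allowed <- pr0 |> dplyr::filter(prior_prob > 0)
  expect_true(all(paste(inferred$from, inferred$to) %in%
                    paste(allowed$from, allowed$to)))
})

test_that("fits export tidy edges, summaries and GraphML", {
  net <- generate_network(4, 0.5, seed = 15, noise_sd = 0)
  des <- full_design(net$node_names)
  fit <- infer_network(simulate_global_response(net, des), des,
                       prior = flat_prior(net$node_names),
                       config = quick_cfg(seed = 2))
  ed <- tidy(fit)
  expect_equal(nrow(ed), 4 * 3)
  expect_true(all(ed$posterior_prob >= 0 & ed$posterior_prob <= 1))
  gl <- glance(fit)
  expect_equal(gl$n_edges, sum(ed$included))

  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(fit, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::gsize(g), gl$n_edges)
  expect_equal(igraph::vcount(g), 4)

  expect_s3_class(autoplot(fit), "ggplot")
})
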