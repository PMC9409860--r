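# Shared fixtures: tiny networks, designs and tables built in code.

# A 2-node cascade: node 1 drives node 2 with local response coefficient 0.5.
cascade2 <- function() {
  r <- matrix(c(-1, 0.5, 0, -1), 2, 2,
              dimnames = list(c("N1", "N2"), c("N1", "N2")))
  structure(list(node_names = c("N1", "N2"), local_response = r,
                 noise_sd = 0, seed = 1L),
            class = "gt_network")
}

# Fully perturbed design: one treatment per node, unit effect.
full_design <- function(nodes, effect = 1) {
  perturbation_design(
    data.frame(treatment = paste0("tx_", nodes), target = nodes,
               effect = effect),
    replicates = 4L
  )
}

# Hand-built analyte table: one cell line, given per-condition replicate
# values (a named list treatment -> numeric replicates), one analyte.
tiny_table <- function(values, analyte = "A1", cell_line = "CL1") {
  purrr::imap(values, function(v, tr) {
    data.frame(cell_line = cell_line, treatment = tr,
               replicate = seq_along(v), analyte = analyte, value = v)
  }) |>
    purrr::list_rbind()
}

# Exact median-effect growth values for given doses.
me_growth <- function(dose, m, dm) {
  fa <- 1 / (1 + (dm / dose)^m)
  1 - fa
}

quick_cfg <- function(seed = 1L, ...) {
  bmra_config(noit = 300L, burnin = 100L, seed = seed, ...)
}
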