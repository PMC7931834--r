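# Shared fixtures built in code.

perfect_assay <- function(specimen = "plasma", platform = "capctm") {
  assay_performance(specimen, platform, 1, 1)
}

# a minimal 3-facility panel: one facility per access class
tiny_panel <- function(totals = c(100, 50, 25), seed = 1) {
  generate_panel(1, 1, 1, totals, seed = seed,
                 transport = list(plasma_only = 10, partial = 20, full = 30))
}

# a two-scenario config over the tiny panel, with simple round numbers
tiny_config <- function() {
  vl_config(
    assays = list(
      plasma_capctm = assay_performance("plasma", "capctm", 0.98, 0.99,
                                        0.95, 0.99, 0.97, 1),
      dbs_capctm = assay_performance("dbs", "capctm", 0.90, 0.92,
                                     0.85, 0.95, 0.88, 0.96)),
    unit_costs = list(
      plasma = specimen_unit_cost("plasma", 1, 2, 10),
      dbs = specimen_unit_cost("dbs", 2, 1, 11)),
    multipliers = list(high_volume = 0.8, low_volume_plasma = 0.4,
                       low_volume_dried = 0.8, unreachable_dried = 0.8),
    epi = list(failure_prevalence = 0.1, correctness_model = "product"),
    visit_transport = list(visit_cost = 2,
                           transport = list(plasma_only = 10, partial = 20, full = 30)),
    scenarios = list(
      scenario_spec("plasma_only", "plasma", "plasma", FALSE,
                    transport_key = "plasma_only"),
      scenario_spec("plasma_dbs", "plasma", "dbs", TRUE,
                    platform_mix = c(capctm = 1), transport_key = "partial")),
    seed = 42)
}

# published (cost, effect) pairs for the five scenarios
printed_pairs <- function() {
  t3 <- table3_printed()
  list(cost = t3$system_cost, effect = t3$correct, names = t3$scenario)
}

# Independent brute-force dominance oracle: strict dominance by pairwise
# comparison, extended dominance by the segment (lower convex hull) test.
# Deliberately written without reference to the iterative-ICER path in
# cea_rank().
oracle_dominance <- function(cost, effect) {
  n <- length(cost)
  status <- rep("undominated", n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && cost[j] <= cost[i] && effect[j] >= effect[i] &&
        (cost[j] < cost[i] || effect[j] > effect[i])) {
      status[i] <- "dominated"
      break
    }
  }
  live <- which(status == "undominated")
  for (i in live) for (j in live) for (k in live) {
    if (effect[j] < effect[i] && effect[i] < effect[k]) {
      interp <- cost[j] + (cost[k] - cost[j]) *
        (effect[i] - effect[j]) / (effect[k] - effect[j])
      if (interp < cost[i]) status[i] <- "weakly_dominated"
    }
  }
  status
}
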