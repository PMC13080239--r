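# Toy network definitions built in code, shared across test files.

# linear chain: clamped substrate -> internal x -> ATP, hyperbolic demand.
# At steady state every flux equals the uptake rate vup * S / (S + km),
# which is the closed-form oracle (the substrate is clamped).
chain_def <- function(s_conc = 2, vup = 1, km = 0.5, vconv = 50, load_rest = 10) {
  list(
    schema_version = 1, name = "toy_chain",
    parameters = list(km_atp = 0.5, load_rest = load_rest,
                      insulin = list(a_ins = 1, k_ins = 200)),
    metabolites = list(
      list(id = "s_e", name = "substrate", compartment = "plasma",
           conc0 = s_conc, boundary = TRUE, carbons = 1),
      list(id = "x", name = "intermediate", compartment = "cytosol",
           conc0 = 0.1, carbons = 1),
      list(id = "atp", name = "ATP", compartment = "cytosol", conc0 = 6),
      list(id = "adp", name = "ADP", compartment = "cytosol", conc0 = 2)),
    pools = list(list(id = "adenine", members = c("atp", "adp"), total = 8)),
    substrate_classes = list(fuel = "s_e"),
    reactions = list(
      list(id = "upt", pathway = "transport",
           stoich = list(s_e = -1, x = 1),
           law = list(form = "irreversible-MM", vmax = vup, km = list(s_e = km)),
           proteins = list("TrpA")),
      list(id = "conv", pathway = "tca",
           stoich = list(x = -1, adp = -1, atp = 1),
           law = list(form = "irreversible-MM", vmax = vconv,
                      km = list(x = 0.01, adp = 0.01)),
           proteins = list("EnzB")),
      list(id = "atp_demand", pathway = "atp-demand",
           stoich = list(atp = -1, adp = 1),
           law = list(form = "load-hyperbolic", vmax = 1, km = list(atp = 0.5)),
           proteins = list())))
}

build_chain <- function(...) build_model(chain_def(...))

# tiny abundance matrix fixture
toy_matrix <- function() {
  m <- rbind(P1 = c(10, 20, 12, 18), P2 = c(5, 5, 10, 10), P3 = c(1, 1, 2, 2))
  colnames(m) <- c("c1", "c2", "t1", "t2")
  abundance_matrix(m, c(c1 = "ctrl", c2 = "ctrl", t1 = "trt", t2 = "trt"))
}

# small cohort configuration used by the heavier end-to-end tests
small_config <- function(...) {
  cohort_config(n_proteins = 400, n_metabolic = 120, ...)
}

# silhouette on a 1-d score vector given group labels
silhouette1d <- function(x, g) {
  vapply(seq_along(x), function(i) {
    a <- mean(abs(x[i] - x[setdiff(which(g == g[i]), i)]))
    b <- min(vapply(setdiff(unique(g), g[i]), function(h) mean(abs(x[i] - x[g == h])),
                    numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}
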