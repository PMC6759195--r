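# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

toy1 <- function() cached("toy1", make_toy_network(toy_spec(n_branch_points = 1)))
toy2 <- function() cached("toy2", make_toy_network(toy_spec(n_branch_points = 2)))

toy2_truth <- function() cached("toy2_truth", {
  sample_ground_truth(toy2(), seed = 4,
                      knockouts = list(dGLY = "GLY", dCLV = "CLV", dPT = "PT"))
})

toy1_truth <- function() cached("toy1_truth", {
  sample_ground_truth(toy1(), seed = 2,
                      knockouts = list(dGLY = "GLY", dCLV = "CLV", dCND = "CND"))
})

toy1_train <- function() cached("toy1_train", {
  truth <- toy1_truth()
  ds <- simulate_dataset(toy1(), truth, noise_cv = 0, seed = 1)
  prepare_training(ds$strain_fluxes, ds$uptakes, wt_strain = "WT",
                   knockouts = ds$knockouts)
})

# the multi-start kinetic parameterization on noise-free toy1 training data;
# computed once and shared between the unit and acceptance tests
toy1_kfit <- function() cached("toy1_kfit", {
  # reverse-flux starts drawn over the generator's own (1, 100) range: the
  # study conditions of the synthetic fixtures
  suppressWarnings(kfit(toy1(), toy1_train(), n_starts = 20, seed = 7,
                        vr_range = c(1, 100), net = toy1_truth()$net))
})

# minimal uni-uni reaction model (boundary metabolites only), optionally with
# one dead-end inhibitor
uni_uni_model <- function(inhibitor_mode = NULL) {
  mets <- tibble::tibble(id = c("A", "P", "I"), carbon_count = 1L,
                         is_extracellular = TRUE)
  rxns <- tibble::tibble(id = "R1", reversible = TRUE)
  st <- tibble::tibble(reaction_id = "R1", metabolite_id = c("A", "P"),
                       coef = c(-1, 1))
  regs <- if (!is.null(inhibitor_mode)) {
    tibble::tibble(reaction_id = "R1", inhibitor_id = "I", mode = inhibitor_mode)
  }
  metabolic_model(mets, rxns, st, regulations = regs)
}

manual_params <- function(net, k_f, k_r) {
  structure(list(k = tibble::tibble(step_id = net$steps$step_id,
                                    k_f = k_f, k_r = k_r)),
            class = "kinetic_params")
}

# tiny 3-reaction linear model with atom maps, for io / EMU basics
linear_model <- function() {
  mets <- tibble::tibble(
    id = c("Aext", "A", "B", "Bext"),
    carbon_count = c(2L, 2L, 2L, 2L),
    is_extracellular = c(TRUE, FALSE, FALSE, TRUE))
  rxns <- tibble::tibble(id = c("IN", "AB", "OUT"), reversible = FALSE,
                         is_uptake = c(TRUE, FALSE, FALSE))
  st <- tibble::tibble(
    reaction_id = c("IN", "IN", "AB", "AB", "OUT", "OUT"),
    metabolite_id = c("Aext", "A", "A", "B", "B", "Bext"),
    coef = c(-1, 1, -1, 1, -1, 1))
  am <- tibble::tibble(
    reaction_id = rep(c("IN", "AB", "OUT"), each = 2),
    mapping_id = 1L, weight = 1,
    role = rep(c("substrate", "product"), 3),
    metabolite_id = c("Aext", "A", "A", "B", "B", "Bext"),
    atoms = rep("ab", 6))
  metabolic_model(mets, rxns, st, am, uptake_reaction = "IN")
}

kinetic_pseudo_fit <- function() {
  cached("pseudo_fit", {
    truth <- toy1_truth()
    m <- toy1()
    ds <- simulate_dataset(m, truth, noise_cv = 0, seed = 1)
    train <- prepare_training(ds$strain_fluxes, ds$uptakes, wt_strain = "WT",
                              knockouts = ds$knockouts)
    structure(list(net = truth$net, params = truth$params, train = train,
                   strain_states = truth$strain_states, ssr = 0,
                   converged = TRUE, start_index = 0),
              class = "kinetic_fit")
  })
}

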