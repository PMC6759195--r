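#' Specification for a synthetic toy network
#'
#' Describes the carbon-balanced toy networks used to exercise the pipeline:
#' a 3-carbon substrate is taken up and processed through two alternative
#' routes that scramble carbon differently (a direct isomerization route and
#' a cleavage/condensation route), so single-route knockouts re-route flux;
#' with two branch points a second split at the common product adds a
#' storage/secretion branch and a biomass-precursor sink.
#'
#' @param n_branch_points 1 (route split only) or 2 (adds the product-side
#'   split and biomass sink).
#' @param regulations Named counts of substrate-level inhibitions to place,
#'   e.g. `c(competitive = 1, uncompetitive = 1, noncompetitive = 1)`.
#' @param seed Seed controlling regulation placement (the topology is fixed
#'   by `n_branch_points`).
#' @return Object of class `toy_spec`.
#' @export
toy_spec <- function(n_branch_points = 2,
                     regulations = c(competitive = 1, uncompetitive = 1,
                                     noncompetitive = 1),
                     seed = 1) {
  if (!n_branch_points %in% 1:2) abort("n_branch_points must be 1 or 2")
  structure(list(n_branch_points = n_branch_points,
                 regulations = regulations, seed = seed),
            class = "toy_spec")
}

#' Generate a carbon-balanced toy metabolic network
#'
#' Deterministic for a fixed spec (including its seed). The returned model
#' passes [validate_model()] with no findings and carries full atom mappings,
#' so it can drive both the labeling (MFA) and kinetic halves of the
#' pipeline.
#'
#' @param spec A [toy_spec()].
#' @return A [metabolic_model()].
#' @export
make_toy_network <- function(spec = toy_spec()) {
  two <- spec$n_branch_points >= 2
  mets <- tibble(
    id = c("Sext", "S", "P", "Q", "X", "Y", "Pext",
           if (two) c("T", "Text")),
    carbon_count = c(3L, 3L, 3L, 3L, 2L, 1L, 3L, if (two) c(3L, 3L)),
    is_extracellular = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                         if (two) c(FALSE, TRUE)),
    is_biomass_precursor = c(FALSE, FALSE, two, FALSE, FALSE, FALSE, FALSE,
                             if (two) c(FALSE, FALSE))
  )
  rxns <- tibble(
    id = c("UPT", "GLY", "CLV", "CND", "ISO", "SEC",
           if (two) c("PT", "TSEC", "PSNK")),
    reversible = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                   if (two) c(FALSE, FALSE, FALSE)),
    is_uptake = c(TRUE, rep(FALSE, 5), if (two) rep(FALSE, 3)),
    is_biomass_sink = c(rep(FALSE, 6), if (two) c(FALSE, FALSE, TRUE))
  )
  sto <- function(rid, ...) {
    co <- c(...)
    tibble(reaction_id = rid, metabolite_id = names(co), coef = unname(co))
  }
  stoich <- bind_rows(
    sto("UPT", Sext = -1, S = 1),
    sto("GLY", S = -1, P = 1),
    sto("CLV", S = -1, X = 1, Y = 1),
    sto("CND", X = -1, Y = -1, Q = 1),
    sto("ISO", Q = -1, P = 1),
    sto("SEC", P = -1, Pext = 1),
    if (two) bind_rows(
      sto("PT", P = -1, T = 1),
      sto("TSEC", T = -1, Text = 1),
      sto("PSNK", P = -1)
    )
  )
  amap <- function(rid, subs, prods) {
    bind_rows(
      tibble(reaction_id = rid, mapping_id = 1L, weight = 1, role = "substrate",
             metabolite_id = names(subs), atoms = unname(subs)),
      tibble(reaction_id = rid, mapping_id = 1L, weight = 1, role = "product",
             metabolite_id = names(prods), atoms = unname(prods))
    )
  }
  atom_maps <- bind_rows(
    amap("UPT", c(Sext = "abc"), c(S = "abc")),
    amap("GLY", c(S = "abc"), c(P = "abc")),
    amap("CLV", c(S = "abc"), c(X = "ab", Y = "c")),
    amap("CND", c(X = "ab", Y = "c"), c(Q = "cab")),
    amap("ISO", c(Q = "abc"), c(P = "abc")),
    amap("SEC", c(P = "abc"), c(Pext = "abc")),
    if (two) bind_rows(
      amap("PT", c(P = "abc"), c(T = "abc")),
      amap("TSEC", c(T = "abc"), c(Text = "abc"))
    )
    # PSNK (biomass sink) is unmapped: its carbon leaves the labeled system
  )

  # place regulations deterministically from the seed
  set.seed(spec$seed)
  cand_rxn <- c("GLY", "CLV", "CND", "ISO", "SEC", if (two) "PT")
  cand_inh <- c("P", "Q", "X", if (two) "T")
  pool <- expand.grid(reaction_id = cand_rxn, inhibitor_id = cand_inh,
                      stringsAsFactors = FALSE)
  own_sub <- stoich |> filter(.data$coef < 0)
  pool <- pool |>
    anti_join(own_sub |> rename(inhibitor_id = "metabolite_id"),
              by = c("reaction_id", "inhibitor_id"))
  regs <- list()
  for (mode in names(spec$regulations)) {
    k <- spec$regulations[[mode]]
    if (k == 0) next
    take <- pool[sample(nrow(pool), k), ]
    pool <- anti_join(pool, take, by = c("reaction_id", "inhibitor_id"))
    regs[[mode]] <- tibble(reaction_id = take$reaction_id,
                           inhibitor_id = take$inhibitor_id, mode = mode)
  }
  regulations <- if (length(regs)) bind_rows(regs) else NULL

  metabolic_model(mets, rxns, stoich, atom_maps, regulations,
                  uptake_reaction = "UPT")
}

#' Default measured fragments and tracer for toy networks
#'
#' The fragment set mixes whole-molecule and sub-molecule fragments of both
#' routes' metabolites so the route split is identifiable from MIDs; the
#' default tracer is 100% substrate labeled at carbon 1.
#'
#' @param model A toy model from [make_toy_network()].
#' @return List with `fragments` tibble and `tracer`.
#' @export
toy_measurements <- function(model) {
  frags <- tibble(
    fragment_id = c("P123", "P12", "P1", "Q12", "X12"),
    metabolite_id = c("P", "P", "P", "Q", "X"),
    atoms = c("1,2,3", "1,2", "1", "1,2", "1,2")
  )
  list(fragments = frags,
       tracer = tracer_spec("Sext", tibble(fraction = 1, pattern = "100")))
}

fragment_pools_active <- function(model, fluxes, metabolite_ids,
                                  min_production = 1e-9) {
  fl <- directional_fluxes(fluxes)
  vf <- setNames(fl$v_f, fl$reaction_id)
  vb <- setNames(fl$v_b, fl$reaction_id)
  prod_flux <- setNames(numeric(length(metabolite_ids)), metabolite_ids)
  for (p in atom_reaction_instances(model)) {
    v <- (if (p$dir == "f") vf[[p$reaction_id]] else vb[[p$reaction_id]]) * p$weight
    hit <- intersect(p$prods$metabolite_id, metabolite_ids)
    prod_flux[hit] <- prod_flux[hit] + v
  }
  extr <- model$metabolites$is_extracellular[
    match(metabolite_ids, model$metabolites$id)]
  unname(prod_flux > min_production | extr)
}

sample_wt_fluxes <- function(model, uptake = 100, min_flux = 2, max_tries = 5000) {
  S <- stoichiometric_matrix(model, balanced_only = TRUE)
  N <- nullspace_basis(S)
  rxn <- model$reactions
  up_i <- match(model$uptake_reaction, rxn$id)
  for (i in seq_len(max_tries)) {
    u <- runif(ncol(N), -1, 1)
    v <- as.numeric(N %*% u)
    if (abs(v[up_i]) < 1e-6) next
    v <- v * uptake / v[up_i]
    if (all(v[!rxn$reversible] >= min_flux) && all(abs(v) >= min_flux)) {
      return(tibble(reaction_id = rxn$id, flux = v))
    }
  }
  abort("could not sample a feasible wild-type flux distribution")
}

#' Sample a ground-truth kinetic parameterization
#'
#' Draws a wild-type flux distribution on the null space of the toy network
#' (uptake normalized to 100), samples enzyme-complex fractions (flat
#' Dirichlet, clipped into (1e-3, 1)) and reverse elementary fluxes
#' (log-uniform), anchors the rate constants to the wild-type state, and
#' resamples until the wild type and all planned knockout strains reach
#' stable steady states.
#'
#' @param model A [make_toy_network()] model.
#' @param seed Random seed (deterministic output for fixed model + seed).
#' @param knockouts Named list: strain id -> enzyme ids deleted.
#' @param vr_range Log-uniform sampling range for reverse elementary fluxes.
#' @param max_tries Resampling budget.
#' @return Object of class `ground_truth`: `params`, `wt_fluxes`,
#'   `wt_state`, `strain_states`, `strain_fluxes`, `knockouts`.
#' @export
sample_ground_truth <- function(model, seed = 1,
                                knockouts = list(dGLY = "GLY", dCLV = "CLV"),
                                vr_range = c(1, 100), max_tries = 50) {
  net <- decompose(model)
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    wt <- sample_wt_fluxes(model)
    e <- numeric(nrow(net$complexes))
    names(e) <- net$complexes$complex_id
    for (enz in unique(net$complexes$enzyme_id)) {
      ids <- net$complexes$complex_id[net$complexes$enzyme_id == enz]
      x <- rgamma(length(ids), 1)
      x <- pmax(x / sum(x), 2e-3); x <- x / sum(x)
      e[ids] <- x
    }
    wt_net <- setNames(wt$flux, wt$reaction_id)
    v_net <- ifelse(net$steps$main_path, wt_net[net$steps$reaction_id], 0)
    lb <- pmax(0, -v_net)
    v_r <- setNames(lb + exp(runif(nrow(net$steps), log(vr_range[1]),
                                   log(vr_range[2]))), net$steps$step_id)
    params <- tryCatch(anchor_wildtype(net, wt, e, v_r), error = function(e) NULL)
    if (is.null(params)) next
    wt_state <- steady_state(net, params)
    if (wt_state$status != "converged") next
    if (!stability_check(net, params, wt_state)$stable) next
    strain_states <- list()
    ok <- TRUE
    for (s in names(knockouts)) {
      lev <- setNames(rep(0, length(knockouts[[s]])), knockouts[[s]])
      st <- steady_state(net, params, enzyme_levels = lev)
      if (st$status != "converged" || !stability_check(net, params, st,
                                                       enzyme_levels = lev)$stable) {
        ok <- FALSE; break
      }
      strain_states[[s]] <- st
    }
    if (!ok) next
    strain_fluxes <- bind_rows(lapply(names(strain_states), function(s)
      strain_states[[s]]$fluxes |> mutate(strain_id = s)))
    return(structure(list(
      net = net, params = params, wt_fluxes = wt, wt_state = wt_state,
      strain_states = strain_states, strain_fluxes = strain_fluxes,
      knockouts = knockouts, seed = seed
    ), class = "ground_truth"))
  }
  abort("no stable ground truth found within the resampling budget")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> stable wild type + ", length(x$strain_states),
      " knockout strain(s), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate a mutant flux training dataset from a ground truth
#'
#' Per-strain MFA-style flux tables: each mutant's true fluxes are
#' renormalized to its own 100-unit uptake basis (as a flux-elucidation step
#' would report them), multiplicative Gaussian noise of coefficient of
#' variation `noise_cv` (truncated at 4 sigma) is applied, and the matching
#' absolute uptake table is emitted so [prepare_training()] can rescale onto
#' the wild-type basis. The wild-type anchor distribution stays noise-free
#' (it must satisfy steady state exactly). Optionally simulates noisy MIDs
#' per strain.
#'
#' @param model The toy model.
#' @param truth A [sample_ground_truth()] result.
#' @param noise_cv Flux noise coefficient of variation (0 = exact).
#' @param seed Seed for the noise.
#' @param mids Logical: also simulate per-strain MIDs (requires atom maps).
#' @param mid_noise_sd Absolute Gaussian noise SD on MID fractions.
#' @return List of class `toy_dataset`: `strain_fluxes` (incl. wild type),
#'   `uptakes`, `knockouts`, and optionally `mids`.
#' @export
simulate_dataset <- function(model, truth, noise_cv = 0, seed = 1,
                             mids = FALSE, mid_noise_sd = 0.003) {
  set.seed(seed)
  up <- model$uptake_reaction
  rows <- list()
  uptakes <- list()
  rows[["WT"]] <- truth$wt_fluxes |>
    mutate(strain_id = "WT", sd = noise_cv * abs(.data$flux))
  uptakes[["WT"]] <- tibble(strain_id = "WT",
                            uptake = truth$wt_fluxes$flux[
                              truth$wt_fluxes$reaction_id == up])
  for (s in names(truth$strain_states)) {
    v <- truth$strain_states[[s]]$fluxes
    up_flux <- v$flux[v$reaction_id == up]
    if (up_flux <= 0) {
      warn(paste0("strain ", s, " has no uptake at truth; skipped"))
      next
    }
    scale <- 100 / up_flux
    noise <- pmin(pmax(rnorm(nrow(v)), -4), 4) * noise_cv
    rows[[s]] <- v |>
      mutate(strain_id = s,
             flux = .data$flux * scale * (1 + noise),
             sd = pmax(noise_cv * abs(.data$flux), 1e-12))
    uptakes[[s]] <- tibble(strain_id = s, uptake = up_flux)
  }
  out <- list(strain_fluxes = bind_rows(rows), uptakes = bind_rows(uptakes),
              knockouts = truth$knockouts)
  if (mids) {
    meas <- toy_measurements(model)
    net <- build_emu_network(model, meas$fragments)
    mid_rows <- list()
    for (s in c("WT", names(truth$strain_states))) {
      fl <- if (s == "WT") truth$wt_fluxes else truth$strain_states[[s]]$fluxes
      # fragments of pathway-inactive pools (zero production in a knockout)
      # have no defined labeling state; a real dataset lacks them, so they
      # are dropped for that strain
      frags <- meas$fragments
      active <- fragment_pools_active(model, fl, frags$metabolite_id)
      frags <- frags[active, , drop = FALSE]
      net_s <- if (all(active)) net else build_emu_network(model, frags)
      m <- simulate_mids(net_s, fl, meas$tracer)
      m$value <- m$value + rnorm(nrow(m), 0, mid_noise_sd)
      mid_rows[[s]] <- m |> mutate(strain_id = s, sd = mid_noise_sd)
    }
    out$mids <- bind_rows(mid_rows)
    out$fragments <- meas$fragments
    out$tracer <- meas$tracer
  }
  structure(out, class = "toy_dataset")
}
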