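#' Decompose a metabolic model into elementary reaction steps
#'
#' Rewrites every enzymatic reaction as an ordered-sequential mechanism of
#' elementary steps among enzyme complexes: substrates bind in order
#' (`E + S1 = ES1`, `ES1 + S2 = ES1S2`, ...), a conversion step releases the
#' first product (`ES... = EP2..Pn + P1`), and remaining products release in
#' order. A reversible uni-uni reaction is thus `E + A = EA = E + P`: 2 steps,
#' 4 rate constants, 2 complexes. Biomass precursor sinks become
#' single-substrate uni mechanisms (`E + A = EA = E`). Substrate-level
#' regulations add dead-end inhibitor-binding steps: competitive inhibitors
#' bind free enzyme only, uncompetitive inhibitors bind the terminal
#' substrate-bound complex only, noncompetitive inhibitors bind both.
#'
#' The decomposition reports its parameter counting: every main-path step has
#' a forward and reverse rate constant (2 per step); every inhibitor-binding
#' step contributes one inhibitor (dead-end dissociation) constant, so a
#' noncompetitive regulation contributes two.
#'
#' @param model A [metabolic_model()]; binding/release orders are taken from
#'   `model$binding_orders`, defaulting to stoichiometry declaration order.
#' @param reactions Optional subset of reaction ids to decompose (default: all
#'   reactions with an enzyme).
#' @return Object of class `elementary_network` with tibbles `steps`
#'   (step_id, reaction_id, enzyme_id, kind, complex_in, complex_out, met_in,
#'   met_out, main_path), `complexes`, and a `counts` list
#'   (`n_elementary_constants`, `n_inhibitor_constants`).
#' @export
decompose <- function(model, reactions = NULL) {
  rxn <- model$reactions
  if (!is.null(reactions)) rxn <- rxn |> filter(.data$id %in% reactions)
  if (anyDuplicated(rxn$enzyme_id)) {
    abort("each reaction must have its own enzyme (one-enzyme-per-reaction map)")
  }
  steps <- list()
  complexes <- list()
  add_step <- function(reaction_id, enzyme_id, kind, cin, cout,
                       met_in = NA_character_, met_out = NA_character_,
                       main_path = TRUE) {
    steps[[length(steps) + 1]] <<- tibble(
      step_id = paste0(reaction_id, ".", length(steps) + 1),
      reaction_id = reaction_id, enzyme_id = enzyme_id, kind = kind,
      complex_in = cin, complex_out = cout,
      met_in = met_in, met_out = met_out, main_path = main_path)
  }

  for (i in seq_len(nrow(rxn))) {
    rid <- rxn$id[i]
    enz <- rxn$enzyme_id[i]
    ord <- reaction_orders(model, rid)
    subs <- ord$substrates
    prods <- ord$products
    free_c <- paste0(enz, ":E")
    cpx <- free_c
    cur <- free_c
    # substrate bindings
    for (s in subs) {
      nxt <- paste0(cur, ":", s)
      add_step(rid, enz, "binding", cur, nxt, met_in = s)
      cpx <- c(cpx, nxt)
      cur <- nxt
    }
    terminal_sub_complex <- cur
    if (length(prods) == 0) {
      # sink: conversion back to free enzyme, substrate leaves the system
      add_step(rid, enz, "conversion", cur, free_c)
    } else {
      rest <- prods[-1]
      nxt <- if (length(rest)) paste0(enz, ":E:", paste(rest, collapse = ":"))
             else free_c
      add_step(rid, enz, "conversion", cur, nxt, met_out = prods[[1]])
      if (length(rest)) cpx <- c(cpx, nxt)
      cur <- nxt
      while (length(rest)) {
        p <- rest[[1]]; rest <- rest[-1]
        nxt <- if (length(rest)) paste0(enz, ":E:", paste(rest, collapse = ":"))
               else free_c
        add_step(rid, enz, "release", cur, nxt, met_out = p)
        if (length(rest)) cpx <- c(cpx, nxt)
        cur <- nxt
      }
    }
    # regulations
    regs <- model$regulations |> filter(.data$reaction_id == rid)
    for (j in seq_len(nrow(regs))) {
      inh <- regs$inhibitor_id[j]
      mode <- regs$mode[j]
      if (mode %in% c("competitive", "noncompetitive")) {
        ic <- paste0(free_c, ":", inh, ":I")
        add_step(rid, enz, "inhibitor_binding", free_c, ic,
                 met_in = inh, main_path = FALSE)
        cpx <- c(cpx, ic)
      }
      if (mode %in% c("uncompetitive", "noncompetitive")) {
        ic <- paste0(terminal_sub_complex, ":", inh, ":I")
        add_step(rid, enz, "inhibitor_binding", terminal_sub_complex, ic,
                 met_in = inh, main_path = FALSE)
        cpx <- c(cpx, ic)
      }
    }
    complexes[[rid]] <- tibble(complex_id = cpx, enzyme_id = enz,
                               is_free = cpx == free_c)
  }

  steps <- bind_rows(steps)
  complexes <- bind_rows(complexes) |> distinct()
  counts <- list(
    n_main_steps = sum(steps$main_path),
    n_elementary_constants = 2L * sum(steps$main_path),
    n_inhibitor_steps = sum(!steps$main_path),
    n_inhibitor_constants = sum(!steps$main_path)
  )
  boundary <- model$metabolites$id[model$metabolites$is_extracellular]
  out <- structure(list(steps = steps, complexes = complexes, counts = counts,
                 reactions = rxn$id,
                 enzymes = unique(rxn$enzyme_id),
                 boundary_metabolites = boundary,
                 balanced_metabolites = setdiff(
                   intersect(model$metabolites$id,
                             unique(model$stoichiometry$metabolite_id)),
                   boundary),
                 stoichiometry = model$stoichiometry,
                 regulations = model$regulations),
            class = "elementary_network")
  out$skeleton <- build_skeleton(out)
  out
}

#' @export
print.elementary_network <- function(x, ...) {
  cat("<elementary_network> ", length(x$reactions), " reactions, ",
      nrow(x$steps), " elementary steps (", x$counts$n_elementary_constants,
      " elementary constants, ", x$counts$n_inhibitor_constants,
      " inhibitor constants)\n", sep = "")
  invisible(x)
}

#' Anchor elementary rate constants to the wild-type flux distribution
#'
#' Given wild-type enzyme-complex fractional abundances `e` (summing to 1 per
#' enzyme) and reverse elementary fluxes `v_r` per step, solves for the unique
#' elementary rate constants that make the wild-type state (all metabolite
#' concentrations scaled to 1, enzyme totals 1) an exact steady state carrying
#' the wild-type net fluxes: each main-path step of a reaction carries the
#' reaction's net flux, so its forward flux is `v_net + v_r`; dead-end
#' inhibitor steps carry zero net flux and are at equilibrium with forward
#' flux `v_r`.
#'
#' @param net An [decompose()] result.
#' @param wt_fluxes Tibble `reaction_id`, `flux` (wild-type, 100-unit uptake
#'   basis).
#' @param e Named vector of complex fractional abundances (names =
#'   `net$complexes$complex_id`).
#' @param v_r Named vector of reverse elementary fluxes per step (names =
#'   `net$steps$step_id`), all > 0.
#' @return Object of class `kinetic_params`: tibble `step_id`, `k_f`, `k_r`
#'   plus the anchoring inputs.
#' @export
anchor_wildtype <- function(net, wt_fluxes, e, v_r) {
  wt <- setNames(wt_fluxes$flux, wt_fluxes$reaction_id)
  st <- net$steps
  esum <- tapply(e[net$complexes$complex_id], net$complexes$enzyme_id, sum)
  if (any(abs(esum - 1) > 1e-8)) {
    abort("complex fractions must sum to 1 per enzyme")
  }
  v_net <- ifelse(st$main_path, wt[st$reaction_id], 0)
  vr <- v_r[st$step_id]
  if (any(!is.finite(vr)) || any(vr < 0)) abort("v_r must be finite and >= 0")
  v_fwd <- v_net + vr
  if (any(v_fwd <= 0)) {
    bad <- st$step_id[v_fwd <= 0]
    abort(paste0("anchoring needs positive forward flux; v_r inconsistent with ",
                 "net flux sign for step(s): ", paste(bad, collapse = ", ")))
  }
  e_in <- e[st$complex_in]
  e_out <- e[st$complex_out]
  # wild-type concentrations are 1 by convention, so rate denominators are the
  # complex abundances alone
  k_f <- as.numeric(v_fwd / e_in)
  k_r <- as.numeric(vr / e_out)
  structure(list(
    k = tibble(step_id = st$step_id, k_f = k_f, k_r = k_r),
    e = e, v_r = vr, wt_fluxes = as_tibble(wt_fluxes)
  ), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params> ", nrow(x$k), " elementary steps anchored\n", sep = "")
  invisible(x)
}

#' Inhibitor (dead-end dissociation) constants of a parameter set
#'
#' One constant per inhibitor-binding step: the association/dissociation ratio
#' `k_f / k_r` (units 1/concentration), the binding affinity that the fitted
#' steady states actually constrain for dead-end steps.
#'
#' @param net An [decompose()] result.
#' @param params A [anchor_wildtype()] result (or any `kinetic_params`).
#' @return Tibble `step_id`, `reaction_id`, `inhibitor_id`, `mode`, `value`.
#' @export
inhibitor_constants <- function(net, params) {
  st <- net$steps |> filter(!.data$main_path)
  k <- params$k
  ki <- k$k_f[match(st$step_id, k$step_id)] / k$k_r[match(st$step_id, k$step_id)]
  modes <- net$regulations
  mode_of <- function(rid, inh) {
    m <- modes$mode[modes$reaction_id == rid & modes$inhibitor_id == inh]
    if (length(m)) m[[1]] else NA_character_
  }
  tibble(step_id = st$step_id, reaction_id = st$reaction_id,
         inhibitor_id = st$met_in,
         mode = map2_chr_(st$reaction_id, st$met_in, mode_of),
         value = ki)
}
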