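#' Assemble a kinetic-parameterization training set
#'
#' Scales each mutant strain's flux distribution onto the wild-type 100-unit
#' basis by the ratio of absolute mutant to wild-type substrate uptake, drops
#' excluded reactions, and applies the weighting floor: the standard deviation
#' used for each residual is `max(1.0, 0.05 * |flux|, SD_MFA)` so that
#' narrow-ranged low-flux reactions are not over-weighted.
#'
#' @param strain_fluxes Tibble `strain_id`, `reaction_id`, `flux`, `sd`
#'   (per-strain distributions, each on its own 100-unit uptake basis). A
#'   list of [fit_fluxes()] results named by strain also works.
#' @param uptakes Tibble `strain_id`, `uptake` (absolute rates), including
#'   the wild type.
#' @param wt_strain Strain id of the wild-type anchor distribution.
#' @param knockouts Named list: strain id -> character vector of enzyme ids
#'   deleted in that strain.
#' @param exclude Reaction ids excluded from fitting (e.g. unresolvable or
#'   energy-metabolism fluxes).
#' @return Object of class `kfit_training`: `targets` (scaled mutant fluxes
#'   with weighting SDs), `wt_fluxes`, `enzyme_levels` per strain.
#' @export
prepare_training <- function(strain_fluxes, uptakes, wt_strain = "WT",
                             knockouts = list(), exclude = character()) {
  if (is.list(strain_fluxes) && !is.data.frame(strain_fluxes)) {
    strain_fluxes <- bind_rows(lapply(names(strain_fluxes), function(s) {
      f <- strain_fluxes[[s]]
      if (inherits(f, "mfa_fit")) f <- f$fluxes
      as_tibble(f) |> mutate(strain_id = s)
    }))
  }
  strain_fluxes <- as_tibble(strain_fluxes)
  if (!"sd" %in% names(strain_fluxes)) strain_fluxes$sd <- 0
  strain_fluxes$sd[is.na(strain_fluxes$sd)] <- 0
  uptakes <- as_tibble(uptakes)
  if (!wt_strain %in% uptakes$strain_id) abort("missing wild-type uptake")
  missing_up <- setdiff(unique(strain_fluxes$strain_id), uptakes$strain_id)
  if (length(missing_up)) {
    abort(paste0("missing absolute uptake for strain(s): ",
                 paste(missing_up, collapse = ", ")))
  }
  wt_up <- uptakes$uptake[uptakes$strain_id == wt_strain]

  wt_fluxes <- strain_fluxes |> filter(.data$strain_id == wt_strain) |>
    select("reaction_id", "flux")

  targets <- strain_fluxes |>
    filter(.data$strain_id != wt_strain, !.data$reaction_id %in% exclude) |>
    left_join(uptakes, by = "strain_id") |>
    mutate(scale = .data$uptake / wt_up,
           flux = .data$flux * .data$scale,
           sd_mfa = .data$sd * .data$scale,
           sd = pmax(1.0, 0.05 * abs(.data$flux), .data$sd_mfa)) |>
    select("strain_id", "reaction_id", "flux", "sd")

  strains <- unique(targets$strain_id)
  levels <- lapply(strains, function(s) {
    ko <- knockouts[[s]] %||% character()
    setNames(rep(0, length(ko)), ko)
  })
  names(levels) <- strains

  structure(list(targets = targets, wt_fluxes = wt_fluxes,
                 enzyme_levels = levels, wt_strain = wt_strain,
                 exclude = exclude),
            class = "kfit_training")
}

#' Variance-weighted SSR between predicted and training fluxes
#'
#' @param pred Named list of [steady_state()] objects (one per training
#'   strain) or a tibble `strain_id`, `reaction_id`, `flux`.
#' @param train A [prepare_training()] result.
#' @return List: `ssr`, `residuals` tibble (with per-flux weighted residual),
#'   `per_strain` SSR shares.
#' @export
compute_ssr <- function(pred, train) {
  if (is.list(pred) && !is.data.frame(pred)) {
    pred <- bind_rows(lapply(names(pred), function(s) {
      p <- pred[[s]]
      if (inherits(p, "steady_state")) p <- p$fluxes
      as_tibble(p) |> mutate(strain_id = s)
    }))
  }
  joined <- train$targets |>
    inner_join(as_tibble(pred), by = c("strain_id", "reaction_id"),
               suffix = c("_obs", "_pred")) |>
    mutate(residual = (.data$flux_pred - .data$flux_obs) / .data$sd)
  per_strain <- joined |> group_by(.data$strain_id) |>
    summarise(ssr = sum(.data$residual^2)) |>
    mutate(share = .data$ssr / sum(.data$ssr))
  list(ssr = sum(joined$residual^2), residuals = joined, per_strain = per_strain)
}

# parameter transform: per enzyme softmax over complexes (first logit pinned
# at 0), per main-path/inhibitor step log(v_r - lower bound)
kfit_transform <- function(net, wt_fluxes) {
  cpx_by_enz <- split(net$complexes$complex_id, net$complexes$enzyme_id)
  wt <- setNames(wt_fluxes$flux, wt_fluxes$reaction_id)
  st <- net$steps
  v_net <- ifelse(st$main_path, wt[st$reaction_id], 0)
  vr_lb <- pmax(0, -v_net) + 1e-9
  nz <- sum(lengths(cpx_by_enz) - 1)
  list(
    cpx_by_enz = cpx_by_enz,
    n_z = nz,
    n_w = nrow(st),
    step_id = st$step_id,
    vr_lb = vr_lb,
    npar = nz + nrow(st),
    to_params = function(theta) {
      z <- theta[seq_len(nz)]
      w <- theta[nz + seq_len(nrow(st))]
      e <- numeric(nrow(net$complexes))
      names(e) <- net$complexes$complex_id
      off <- 0
      for (enz in names(cpx_by_enz)) {
        ids <- cpx_by_enz[[enz]]
        m <- length(ids)
        zz <- c(0, z[off + seq_len(m - 1)])
        zz <- zz - max(zz)
        e[ids] <- exp(zz) / sum(exp(zz))
        off <- off + m - 1
      }
      v_r <- setNames(vr_lb + exp(w), st$step_id)
      list(e = e, v_r = v_r)
    },
    from_params = function(e, v_r) {
      z <- numeric(0)
      for (enz in names(cpx_by_enz)) {
        ids <- cpx_by_enz[[enz]]
        z <- c(z, log(e[ids[-1]]) - log(e[ids[1]]))
      }
      w <- log(pmax(v_r[st$step_id] - vr_lb, 1e-12))
      c(z, w)
    }
  )
}

#' Fit elementary kinetic parameters to mutant flux distributions (K-FIT)
#'
#' The outer parameter estimation: for each randomly initialized start,
#' wild-type enzyme-complex fractions `e` and reverse elementary fluxes `v_r`
#' are sampled, anchored to the wild-type flux distribution
#' ([anchor_wildtype()]), every training strain's steady state is evaluated
#' ([steady_state()]), and the variance-weighted SSR against the training
#' fluxes is minimized by gradient-based (Levenberg-Marquardt) local search on
#' transformed variables (per-enzyme logits for `e`, log for `v_r`).
#' Non-convergent or unstable inner evaluations are penalized so the line
#' search rejects them.
#'
#' @param model A [metabolic_model()].
#' @param train A [prepare_training()] result.
#' @param n_starts Number of random multi-starts.
#' @param seed Base seed; start `i` uses `seed + i`.
#' @param vr_range Log-uniform initialization range for reverse elementary
#'   fluxes.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @param init_theta Optional list of transformed parameter vectors used as
#'   the first starts (e.g. a previous fit's optimum, for warm-started
#'   refits); remaining starts are sampled randomly.
#' @param net Optional pre-built [decompose()] result.
#' @return List of `kinetic_fit` objects sorted by SSR (class `kfit_results`).
#'   Each has `params` ([anchor_wildtype()] result), `ssr`, `residuals`,
#'   `strain_states`, `converged`, `start_index`.
#' @export
kfit <- function(model, train, n_starts = 20, seed = 1,
                 vr_range = c(1e-3, 1e4), maxiter = 100, init_theta = NULL,
                 net = NULL) {
  if (is.null(net)) net <- decompose(model)
  tr <- kfit_transform(net, train$wt_fluxes)
  strains <- names(train$enzyme_levels)
  targets_by_strain <- split(train$targets, train$targets$strain_id)
  n_res <- nrow(train$targets)

  warm <- new.env(parent = emptyenv())
  objective <- function(theta) {
    p <- tr$to_params(theta)
    params <- tryCatch(anchor_wildtype(net, train$wt_fluxes, p$e, p$v_r),
                       error = function(e) NULL)
    if (is.null(params)) return(rep(1e3, n_res))
    res <- numeric(0)
    for (s in strains) {
      ss <- tryCatch(suppressWarnings(
        steady_state(net, params, enzyme_levels = train$enzyme_levels[[s]],
                     c0 = warm[[s]], tol = 1e-9, max_iter = 40,
                     newton_gate = Inf, relax_on_stall = FALSE)),
        error = function(e) NULL)
      if (is.null(ss)) {
        res <- c(res, rep(1e3, nrow(targets_by_strain[[s]])))
        next
      }
      if (ss$status != "converged") {
        res <- c(res, rep(1e3, nrow(targets_by_strain[[s]])))
        next
      }
      warm[[s]] <- setNames(ss$concentrations$conc, ss$concentrations$metabolite_id)
      v <- setNames(ss$fluxes$flux, ss$fluxes$reaction_id)
      tg <- targets_by_strain[[s]]
      res <- c(res, (v[tg$reaction_id] - tg$flux) / tg$sd)
    }
    # soft bound on v_r upper range
    pen <- pmax(0, log(p$v_r) - log(vr_range[2])) * 10
    c(res, pen)
  }

  run_lm <- function(theta0) {
    tryCatch(
      minpack.lm::nls.lm(theta0, fn = objective,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL)
  }

  fits <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    set.seed(seed + i)
    theta0 <- if (i <= length(init_theta)) init_theta[[i]]
              else sample_start_theta(net, tr, vr_range)
    rm(list = ls(warm), envir = warm)
    fitted <- run_lm(theta0)
    if (is.null(fitted)) next
    # a fresh LM round from the optimum resets the damping schedule and
    # finishes off shallow tails of good basins
    if (sum(objective(fitted$par)^2) < 10 * n_res) {
      refit <- run_lm(fitted$par)
      if (!is.null(refit)) fitted <- refit
    }
    res <- objective(fitted$par)
    ssr <- sum(res[seq_len(n_res)]^2)
    p <- tr$to_params(fitted$par)
    params <- anchor_wildtype(net, train$wt_fluxes, p$e, p$v_r)
    states <- lapply(strains, function(s)
      suppressWarnings(
        steady_state(net, params, enzyme_levels = train$enzyme_levels[[s]],
                     c0 = warm[[s]], tol = 1e-9, max_iter = 200,
                     newton_gate = Inf, relax_on_stall = FALSE)))
    names(states) <- strains
    all_conv <- all(map_chr(states, "status") == "converged")
    sc <- compute_ssr(states, train)
    fits[[i]] <- structure(list(
      params = params, theta = fitted$par, ssr = if (all_conv) sc$ssr else ssr,
      residuals = sc$residuals, per_strain = sc$per_strain,
      strain_states = states, converged = all_conv, lm_info = fitted$info,
      start_index = i, seed = seed, net = net, train = train,
      transform = tr
    ), class = "kinetic_fit")
  }
  fits <- fits[!map_lgl(fits, is.null)]
  fits <- fits[map_lgl(fits, function(f) f$converged)]
  if (!length(fits)) abort("no kinetic parameterization start converged")
  fits <- fits[order(map_dbl(fits, "ssr"))]
  structure(fits, class = "kfit_results")
}

sample_start_theta <- function(net, tr, vr_range) {
  z <- numeric(0)
  for (enz in names(tr$cpx_by_enz)) {
    m <- length(tr$cpx_by_enz[[enz]])
    # flat Dirichlet over the simplex, truncated away from the (1e-3, 1) edges
    e <- rgamma(m, 1)
    e <- pmin(pmax(e / sum(e), 2e-3), 1 - 1e-3)
    e <- e / sum(e)
    z <- c(z, log(e[-1]) - log(e[1]))
  }
  w <- log(exp(runif(tr$n_w, log(vr_range[1]), log(vr_range[2]))))
  c(z, w)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit> SSR ", signif(x$ssr, 5), " (start ", x$start_index,
      if (x$converged) ", converged" else ", NOT converged", ")\n", sep = "")
  invisible(x)
}

#' @export
print.kfit_results <- function(x, ...) {
  cat("<kfit_results> ", length(x), " converged local minima; best SSR ",
      signif(x[[1]]$ssr, 5), "\n", sep = "")
  invisible(x)
}

#' Model acceptance and recovery rate
#'
#' Applies the acceptance rules to a multi-start fit: the best model is
#' accepted only if (a) at least one other local minimum has an SSR within
#' 10% of the best SSR (solution reproducibility) and (b) the best model
#' yields stable steady states for every supplied validation perturbation.
#' The recovery rate is the fraction of converged starts whose mean squared
#' flux deviation from the best model is at most 0.05 per reaction flux.
#'
#' @param results A [kfit()] result list.
#' @param validation_levels Optional list of named enzyme-level vectors
#'   (perturbations that must admit a stable steady state).
#' @param neighbor_frac Reproducibility window (0.10 = within 10% of best
#'   SSR).
#' @param recovery_tol Mean squared flux deviation defining solution recovery.
#' @return Object of class `kfit_selection`: `best`, `neighbors`,
#'   `recovery_rate`, `accepted`, `stability` tibble.
#' @export
accept_models <- function(results, validation_levels = list(),
                          neighbor_frac = 0.10, recovery_tol = 0.05) {
  ssrs <- map_dbl(results, "ssr")
  best <- results[[which.min(ssrs)]]
  neighbors <- which(ssrs <= (1 + neighbor_frac) * min(ssrs))
  neighbors <- setdiff(neighbors, which.min(ssrs))

  best_flux <- bind_rows(lapply(names(best$strain_states), function(s)
    best$strain_states[[s]]$fluxes |> mutate(strain_id = s)))
  recov <- map_lgl(results, function(f) {
    fl <- bind_rows(lapply(names(f$strain_states), function(s)
      f$strain_states[[s]]$fluxes |> mutate(strain_id = s)))
    j <- inner_join(fl, best_flux, by = c("strain_id", "reaction_id"),
                    suffix = c("", "_best"))
    mean((j$flux - j$flux_best)^2) <= recovery_tol
  })

  stab <- tibble(perturbation = character(), status = character(),
                 stable = logical())
  all_stable <- TRUE
  if (length(validation_levels)) {
    rows <- list()
    for (nm in names(validation_levels)) {
      ss <- steady_state(best$net, best$params,
                         enzyme_levels = validation_levels[[nm]])
      stbl <- if (ss$status == "converged") {
        stability_check(best$net, best$params, ss)$stable
      } else FALSE
      rows[[nm]] <- tibble(perturbation = nm, status = ss$status, stable = stbl)
    }
    stab <- bind_rows(rows)
    all_stable <- all(stab$stable)
  }

  structure(list(
    best = best,
    neighbor_indices = neighbors,
    ssrs = ssrs,
    recovery_rate = mean(recov),
    accepted = length(neighbors) >= 1 && all_stable,
    stability = stab
  ), class = "kfit_selection")
}

#' @export
print.kfit_selection <- function(x, ...) {
  cat("<kfit_selection> best SSR ", signif(min(x$ssrs), 5), "; ",
      length(x$neighbor_indices), " neighbor(s) within 10%; recovery rate ",
      signif(100 * x$recovery_rate, 3), "%; ",
      if (x$accepted) "accepted" else "NOT accepted", "\n", sep = "")
  invisible(x)
}

#' Leave-one-out cross-validation of a kinetic parameterization
#'
#' Refits the kinetic model with one mutant strain removed from the training
#' set. Starts are initialized until either a model beats the full fit's best
#' SSR, or the running recovery rate falls below the full fit's recovery
#' rate (whichever comes first), up to `max_starts`. The held-out strain's
#' flux distribution is then predicted and its SSR reported.
#'
#' @param model A [metabolic_model()].
#' @param train A [prepare_training()] result.
#' @param held_out_strain Strain id to remove.
#' @param full_fit A [accept_models()] selection from the full fit (supplies
#'   the stopping thresholds); may be `NULL` to just use `max_starts`.
#' @param init_theta Optional warm start for the first refit attempt
#'   (typically the full fit's optimum).
#' @param max_starts Start budget.
#' @inheritParams kfit
#' @return Object of class `kfit_cv`: the refit (`fit`), `held_out_ssr`,
#'   `fitted_ssr`, `n_starts_used`, `recovery_rate`, and predicted vs
#'   training uptake for the held-out strain.
#' @export
cross_validate <- function(model, train, held_out_strain, full_fit = NULL,
                           init_theta = NULL, max_starts = 20, seed = 1,
                           net = NULL, ...) {
  if (!held_out_strain %in% names(train$enzyme_levels)) {
    abort(paste0("held-out strain not in training set: ", held_out_strain))
  }
  sub <- train
  sub$targets <- train$targets |> filter(.data$strain_id != held_out_strain)
  sub$enzyme_levels <- train$enzyme_levels[
    setdiff(names(train$enzyme_levels), held_out_strain)]

  if (is.null(net)) net <- decompose(model)
  full_best <- if (!is.null(full_fit)) min(full_fit$ssrs) else -Inf
  full_recovery <- if (!is.null(full_fit)) full_fit$recovery_rate else 0

  fits <- list()
  used <- 0
  repeat {
    used <- used + 1
    batch <- tryCatch(
      kfit(model, sub, n_starts = 1, seed = seed + 1000 * used, net = net,
           init_theta = if (used == 1 && !is.null(init_theta))
             list(init_theta) else NULL, ...),
      error = function(e) NULL)
    if (!is.null(batch)) fits <- c(fits, unclass(batch))
    if (length(fits)) {
      best_ssr <- min(map_dbl(fits, "ssr"))
      sel <- accept_models(structure(fits, class = "kfit_results"))
      if (best_ssr < full_best) break
      if (used >= 3 && sel$recovery_rate < full_recovery) break
    }
    if (used >= max_starts) break
  }
  if (!length(fits)) abort("cross-validation: no start converged")
  fits <- fits[order(map_dbl(fits, "ssr"))]
  best <- fits[[1]]

  ho_levels <- train$enzyme_levels[[held_out_strain]]
  ho_state <- steady_state(net, best$params, enzyme_levels = ho_levels)
  ho_targets <- train$targets |> filter(.data$strain_id == held_out_strain)
  ho <- train; ho$targets <- ho_targets
  ho_ssr <- if (ho_state$status == "converged") {
    compute_ssr(setNames(list(ho_state), held_out_strain), ho)$ssr
  } else Inf

  structure(list(
    held_out_strain = held_out_strain,
    fit = best,
    fits = fits,
    held_out_ssr = ho_ssr,
    fitted_ssr = best$ssr,
    n_starts_used = used,
    recovery_rate = accept_models(structure(fits, class = "kfit_results"))$recovery_rate,
    held_out_state = ho_state,
    predicted_uptake = if (!is.na(model$uptake_reaction) &&
                           ho_state$status == "converged")
      ho_state$fluxes$flux[ho_state$fluxes$reaction_id == model$uptake_reaction]
    else NA_real_,
    training_uptake = if (!is.na(model$uptake_reaction)) {
      tg <- ho_targets |> filter(.data$reaction_id == model$uptake_reaction)
      if (nrow(tg)) tg$flux[[1]] else NA_real_
    } else NA_real_
  ), class = "kfit_cv")
}

#' @export
print.kfit_cv <- function(x, ...) {
  cat("<kfit_cv> held out ", x$held_out_strain, ": fitted SSR ",
      signif(x$fitted_ssr, 5), ", held-out SSR ", signif(x$held_out_ssr, 5),
      " (", x$n_starts_used, " starts)\n", sep = "")
  invisible(x)
}
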