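#' Covariance from a residual Jacobian
#'
#' The linear-algebra core of the sensitivity analysis: given the Jacobian
#' `J` of (weighted) residuals with respect to parameters and optional
#' residual weights `w` (so `W = diag(w^2)` in `H = J'WJ`), returns the
#' Gauss-Newton Hessian approximation, its pseudo-inverse covariance on the
#' identifiable subspace, and each parameter's loading on null directions.
#'
#' @param J Residuals-by-parameters Jacobian matrix.
#' @param w Optional per-residual weights (1/SD); defaults to 1 (already
#'   weighted residuals).
#' @param svd_cutoff Relative singular-value cutoff defining null directions.
#' @return List with `H`, `covariance`, `null_load`.
#' @export
covariance_from_jacobian <- function(J, w = NULL, svd_cutoff = 1e-10) {
  if (!is.null(w)) J <- J * w
  H <- crossprod(J)
  sv <- svd(H)
  keep <- sv$d > svd_cutoff * max(sv$d)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  covariance <- sv$v %*% (dinv * t(sv$u))
  null_load <- if (any(!keep)) {
    rowSums(abs(sv$v[, !keep, drop = FALSE]))
  } else rep(0, ncol(J))
  list(H = H, covariance = covariance, null_load = null_load)
}

kfit_residuals_of_k <- function(fit, kvec) {
  net <- fit$net
  train <- fit$train
  params <- fit$params
  n <- nrow(params$k)
  params$k$k_f <- kvec[seq_len(n)]
  params$k$k_r <- kvec[n + seq_len(n)]
  res <- numeric(0)
  for (s in names(train$enzyme_levels)) {
    ss <- steady_state(net, params, enzyme_levels = train$enzyme_levels[[s]],
                       c0 = setNames(fit$strain_states[[s]]$concentrations$conc,
                                     fit$strain_states[[s]]$concentrations$metabolite_id),
                       tol = 1e-10, max_iter = 200)
    tg <- train$targets |> filter(.data$strain_id == s)
    if (ss$status != "converged") {
      res <- c(res, rep(1e3, nrow(tg)))
      next
    }
    v <- setNames(ss$fluxes$flux, ss$fluxes$reaction_id)
    res <- c(res, (v[tg$reaction_id] - tg$flux) / tg$sd)
  }
  res
}

#' Covariance-based sensitivity of elementary kinetic parameters
#'
#' Numerically differentiates the vector of weighted flux residuals with
#' respect to every elementary rate constant (central differences, relative
#' step `rel_step`), approximates the Hessian as `H = J'WJ` (residuals are
#' pre-weighted so W is the identity here), inverts it on the identifiable
#' subspace (singular values below `svd_cutoff * sigma_max` are treated as
#' null directions), and reports per-parameter standard deviations and
#' coefficients of variation `CV(%) = 100 * SD / value`. Parameters with
#' appreciable weight in a null direction are flagged unidentifiable.
#'
#' @param fit A converged `kinetic_fit` (element of a [kfit()] result).
#' @param rel_step Relative finite-difference step.
#' @param svd_cutoff Relative singular-value cutoff for the pseudo-inverse.
#' @return Object of class `sensitivity_report`: `parameters` tibble
#'   (`name`, `step_id`, `which` (`k_f`/`k_r`), `value`, `sd`, `cv_pct`,
#'   `identifiable`), plus `J`, `H`, `covariance`.
#' @export
sensitivity <- function(fit, rel_step = 1e-5, svd_cutoff = 1e-10) {
  k0 <- c(fit$params$k$k_f, fit$params$k$k_r)
  n <- nrow(fit$params$k)
  names(k0) <- c(paste0("kf.", fit$params$k$step_id),
                 paste0("kr.", fit$params$k$step_id))
  r0 <- kfit_residuals_of_k(fit, k0)
  J <- matrix(0, length(r0), length(k0), dimnames = list(NULL, names(k0)))
  for (j in seq_along(k0)) {
    h <- rel_step * max(abs(k0[j]), 1e-8)
    kp <- k0; kp[j] <- k0[j] + h
    km <- k0; km[j] <- k0[j] - h
    J[, j] <- (kfit_residuals_of_k(fit, kp) - kfit_residuals_of_k(fit, km)) / (2 * h)
  }
  cv <- covariance_from_jacobian(J, svd_cutoff = svd_cutoff)
  H <- cv$H
  covariance <- cv$covariance
  dimnames(covariance) <- list(names(k0), names(k0))
  vars <- pmax(diag(covariance), 0)
  null_load <- cv$null_load
  params <- tibble(
    name = names(k0),
    step_id = rep(fit$params$k$step_id, 2),
    which = rep(c("k_f", "k_r"), each = n),
    value = as.numeric(k0),
    sd = sqrt(vars),
    cv_pct = 100 * sqrt(vars) / abs(as.numeric(k0)),
    identifiable = null_load < 1e-6
  )
  structure(list(parameters = params, J = J, H = H, covariance = covariance),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report> ", nrow(x$parameters), " parameters, ",
      sum(!x$parameters$identifiable), " flagged unidentifiable\n", sep = "")
  invisible(x)
}

#' Classify substrate-level regulations as essential or dispensable
#'
#' A regulation is nonessential when the one-standard-deviation range of its
#' inhibitor constant has a lower bound of zero or below, i.e.
#' `value - SD <= 0`; otherwise it is essential to model fitness. The
#' inhibitor constant of a dead-end binding step is `k_f / k_r`; its SD is
#' propagated from the elementary-constant covariance by the delta method.
#'
#' @param fit A converged `kinetic_fit`.
#' @param report A [sensitivity()] result for `fit` (computed if missing).
#' @return Object of class `regulation_essentiality`: tibble `step_id`,
#'   `reaction_id`, `inhibitor_id`, `mode`, `value`, `sd`, `essential`,
#'   plus summary counts.
#' @export
essential_regulations <- function(fit, report = NULL) {
  if (is.null(report)) report <- sensitivity(fit)
  ki <- inhibitor_constants(fit$net, fit$params)
  if (!nrow(ki)) {
    out <- ki |> mutate(sd = double(0), essential = logical(0))
  } else {
    cv <- report$covariance
    sds <- map_dbl(seq_len(nrow(ki)), function(i) {
      sid <- ki$step_id[i]
      nf <- paste0("kf.", sid); nr <- paste0("kr.", sid)
      kf <- fit$params$k$k_f[fit$params$k$step_id == sid]
      kr <- fit$params$k$k_r[fit$params$k$step_id == sid]
      g <- c(1 / kr, -kf / kr^2)  # d(kf/kr)/d(kf, kr)
      v <- t(g) %*% cv[c(nf, nr), c(nf, nr)] %*% g
      sqrt(max(as.numeric(v), 0))
    })
    out <- ki |> mutate(sd = sds, essential = (.data$value - .data$sd) > 0)
  }
  structure(list(
    regulations = out,
    n_essential = sum(out$essential),
    n_total = nrow(out)
  ), class = "regulation_essentiality")
}

#' @export
print.regulation_essentiality <- function(x, ...) {
  cat("<regulation_essentiality> ", x$n_essential, " of ", x$n_total,
      " regulations essential\n", sep = "")
  invisible(x)
}

#' Michaelis-Menten parameter ranges across accepted models
#'
#' For every model within `neighbor_frac` of the optimal SSR and for
#' metabolite concentrations one standard deviation above and one below
#' their means (the two scaling corners), evaluates each derived Km term and
#' Vmax; the reported range is the min/max over that models-by-corners grid.
#' Unscaled elementary-parameter ranges are one SD above/below the
#' across-model mean. Parameters whose scaling concentrations are missing
#' from `metabolomics` are skipped.
#'
#' @param results A [kfit()] result list.
#' @param metabolomics Tibble `metabolite_id`, `mean`, `sd` (absolute
#'   concentrations).
#' @param reactions Reactions to derive (default: all with a mechanism).
#' @param neighbor_frac SSR window defining the model set.
#' @return Object of class `mm_ranges`: `km` tibble (`reaction_id`,
#'   `monomial`, `value`, `lo`, `hi`), `vmax` tibble, `elementary` tibble.
#' @export
mm_ranges <- function(results, metabolomics, reactions = NULL,
                      neighbor_frac = 0.10) {
  metabolomics <- as_tibble(metabolomics)
  ssrs <- map_dbl(results, "ssr")
  models <- results[ssrs <= (1 + neighbor_frac) * min(ssrs)]
  net <- models[[1]]$net
  reactions <- reactions %||% unique(net$steps$reaction_id)

  corners <- list(lo = pmax(metabolomics$mean - metabolomics$sd, 1e-12),
                  hi = metabolomics$mean + metabolomics$sd)
  km_rows <- list(); vmax_rows <- list()
  for (rid in reactions) {
    species <- unique(c(net$steps$met_in[net$steps$reaction_id == rid],
                        net$steps$met_out[net$steps$reaction_id == rid]))
    species <- species[!is.na(species)]
    if (!all(species %in% metabolomics$metabolite_id)) next
    vals_km <- list(); vals_vmax <- numeric(0)
    for (m in models) {
      for (corner in names(corners)) {
        conc <- setNames(corners[[corner]], metabolomics$metabolite_id)
        law <- king_altman(net, rid, params = scale_params(net, m$params, conc))
        vals_km[[paste(m$start_index, corner)]] <- law$km
        vals_vmax <- c(vals_vmax, law$vmax_f)
      }
    }
    all_km <- bind_rows(vals_km)
    km_rows[[rid]] <- all_km |>
      group_by(.data$monomial) |>
      summarise(lo = min(.data$value), hi = max(.data$value),
                value = mean(.data$value), .groups = "drop") |>
      select("monomial", "value", "lo", "hi") |>
      mutate(reaction_id = rid)
    vmax_rows[[rid]] <- tibble(reaction_id = rid,
                               value = mean(vals_vmax),
                               lo = min(vals_vmax), hi = max(vals_vmax))
  }

  kmat <- do.call(rbind, lapply(models, function(m) c(m$params$k$k_f, m$params$k$k_r)))
  colnames(kmat) <- c(paste0("kf.", models[[1]]$params$k$step_id),
                      paste0("kr.", models[[1]]$params$k$step_id))
  elementary <- tibble(
    name = colnames(kmat),
    value = colMeans(kmat),
    lo = colMeans(kmat) - apply(kmat, 2, sd),
    hi = colMeans(kmat) + apply(kmat, 2, sd)
  )
  structure(list(km = bind_rows(km_rows), vmax = bind_rows(vmax_rows),
                 elementary = elementary, n_models = length(models)),
            class = "mm_ranges")
}

#' @export
print.mm_ranges <- function(x, ...) {
  cat("<mm_ranges> ", nrow(x$km), " Km terms / ", nrow(x$vmax),
      " Vmax over ", x$n_models, " model(s)\n", sep = "")
  invisible(x)
}
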