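#' Simulate an engineered strain by enzyme-level fold changes
#'
#' An x-fold change in gene expression is modeled as an x-fold change in the
#' total enzyme level of the corresponding reaction (applied to all of its
#' enzyme complexes); fold 0 is a knockout. Unperturbed enzymes stay at the
#' wild-type level.
#'
#' @param fit A converged `kinetic_fit` (element of a [kfit()] result).
#' @param spec Tibble `reaction_id`, `fold` (fold >= 0).
#' @return A [steady_state()] for the perturbed strain; non-convergent or
#'   unstable evaluations are returned with their status so callers can
#'   propagate them.
#' @export
apply_perturbation <- function(fit, spec) {
  spec <- as_tibble(spec)
  if (any(spec$fold < 0)) abort("fold changes must be >= 0")
  st <- fit$net$steps
  enz_of <- st |> distinct(.data$reaction_id, .data$enzyme_id)
  bad <- setdiff(spec$reaction_id, enz_of$reaction_id)
  if (length(bad)) {
    abort(paste0("perturbation names unknown reaction(s): ",
                 paste(bad, collapse = ", ")))
  }
  levels <- setNames(spec$fold,
                     enz_of$enzyme_id[match(spec$reaction_id, enz_of$reaction_id)])
  steady_state(fit$net, fit$params, enzyme_levels = levels)
}

#' Predict a product yield from a perturbed steady state
#'
#' Yield is the target reaction flux divided by the substrate uptake flux
#' (mol product per mol substrate), both taken from the perturbed state. When
#' the product's pathway is outside the model, a producing/consuming reaction
#' of its precursor serves as an explicit proxy target.
#'
#' @param state A converged [steady_state()].
#' @param target_reaction Reaction whose flux measures product formation (or
#'   a character vector of reactions whose fluxes are summed, for lumped
#'   targets).
#' @param uptake_reaction Substrate uptake reaction.
#' @param experimental Optional experimental yield for the percent
#'   overprediction `100 * (pred - exp) / exp`.
#' @return Object of class `yield_prediction`: `yield`, `target_flux`,
#'   `uptake_flux`, `stable`, `percent_overprediction`.
#' @export
predict_yield <- function(state, target_reaction, uptake_reaction,
                          experimental = NULL) {
  if (state$status != "converged") {
    abort(paste0("state is ", state$status, "; no yield can be predicted"))
  }
  v <- setNames(state$fluxes$flux, state$fluxes$reaction_id)
  bad <- setdiff(c(target_reaction, uptake_reaction), names(v))
  if (length(bad)) abort(paste0("unknown reaction(s): ", paste(bad, collapse = ", ")))
  uptake <- v[[uptake_reaction]]
  if (uptake <= 0) {
    abort("predicted no carbon uptake (uptake flux <= 0); yield undefined")
  }
  target <- sum(v[target_reaction])
  yield <- target / uptake
  over <- if (!is.null(experimental)) 100 * (yield - experimental) / experimental
          else NA_real_
  structure(list(yield = yield, target_flux = target, uptake_flux = uptake,
                 stable = TRUE, experimental = experimental %||% NA_real_,
                 percent_overprediction = over),
            class = "yield_prediction")
}

#' @export
print.yield_prediction <- function(x, ...) {
  cat("<yield_prediction> yield ", signif(x$yield, 4), " mol/mol",
      if (!is.na(x$percent_overprediction))
        paste0(" (", sprintf("%+.0f", x$percent_overprediction),
               "% vs experimental ", signif(x$experimental, 3), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Summarize fit quality of predicted versus training fluxes
#'
#' Reports the fraction of fitted fluxes falling within one, two, three and
#' four weighting standard deviations of the training values, the Pearson
#' correlation of predicted versus training fluxes, and per-strain SSR
#' shares.
#'
#' @param pred Named list of [steady_state()] objects or tibble `strain_id`,
#'   `reaction_id`, `flux`.
#' @param train A [prepare_training()] result.
#' @return Object of class `kfit_summary`: `within_sd` tibble (`n_sd`,
#'   `fraction`), `pearson_r`, `per_strain`, `residuals`.
#' @export
fit_summary <- function(pred, train) {
  sc <- compute_ssr(pred, train)
  j <- sc$residuals
  within <- tibble(
    n_sd = 1:4,
    fraction = map_dbl(1:4, function(k) mean(abs(j$residual) <= k))
  )
  structure(list(
    within_sd = within,
    pearson_r = cor(j$flux_pred, j$flux_obs),
    per_strain = sc$per_strain,
    residuals = j,
    ssr = sc$ssr,
    mean_sq_residual = sc$ssr / nrow(j)
  ), class = "kfit_summary")
}

#' @export
print.kfit_summary <- function(x, ...) {
  cat("<kfit_summary> SSR ", signif(x$ssr, 5), ", mean weighted squared ",
      "residual ", signif(x$mean_sq_residual, 3), "\n", sep = "")
  cat("  within 1/2/3/4 SD: ",
      paste0(round(100 * x$within_sd$fraction), "%", collapse = " / "),
      "; Pearson r = ", signif(x$pearson_r, 4), "\n", sep = "")
  invisible(x)
}
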