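#' Tidy a 13C-MFA flux fit
#'
#' @param x An [fit_fluxes()] result.
#' @param ... Unused.
#' @return Tibble with one row per reaction: `reaction_id`, `flux`, `exch`,
#'   `sd`.
#' @method tidy mfa_fit
#' @export
tidy.mfa_fit <- function(x, ...) x$fluxes

#' @rdname tidy.mfa_fit
#' @method glance mfa_fit
#' @export
glance.mfa_fit <- function(x, ...) {
  tibble(ssr = x$ssr, dof = x$dof, n_starts = x$n_starts,
         convergence_fraction = x$convergence_fraction, accepted = x$accepted)
}

#' Tidy a kinetic parameterization fit
#'
#' @param x A `kinetic_fit` (element of a [kfit()] result).
#' @param ... Unused.
#' @return One row per elementary rate constant: `step_id`, `k_f`, `k_r`,
#'   wild-type `e_in`, `v_r`.
#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  st <- x$net$steps
  x$params$k |>
    mutate(reaction_id = st$reaction_id,
           kind = st$kind,
           v_r = as.numeric(x$params$v_r[.data$step_id]))
}

#' @rdname tidy.kinetic_fit
#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(ssr = x$ssr, n_residuals = nrow(x$residuals),
         mean_sq_residual = x$ssr / nrow(x$residuals),
         converged = x$converged, start_index = x$start_index)
}

#' Tidy a steady state
#'
#' @param x A [steady_state()] result.
#' @param ... Unused.
#' @return Tibble `reaction_id`, `flux`.
#' @method tidy steady_state
#' @export
tidy.steady_state <- function(x, ...) x$fluxes

#' @rdname tidy.steady_state
#' @method glance steady_state
#' @export
glance.steady_state <- function(x, ...) {
  tibble(status = x$status, max_dcdt = x$max_dcdt)
}

#' Tidy a sensitivity report
#'
#' @param x A [sensitivity()] result.
#' @param ... Unused.
#' @method tidy sensitivity_report
#' @export
tidy.sensitivity_report <- function(x, ...) x$parameters

#' Tidy a regulation-essentiality verdict
#'
#' @param x An [essential_regulations()] result.
#' @param ... Unused.
#' @method tidy regulation_essentiality
#' @export
tidy.regulation_essentiality <- function(x, ...) x$regulations

#' Plot fit quality of a kinetic parameterization
#'
#' Parity plot of predicted versus training fluxes, colored by strain, with
#' the identity line; the standard companion to the within-SD summary.
#'
#' @param object A [fit_summary()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kfit_summary
#' @export
autoplot.kfit_summary <- function(object, ...) {
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(x = .data$flux_obs, y = .data$flux_pred,
                               color = .data$strain_id)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "training flux (mmol/100 mmol uptake)",
                  y = "predicted flux", color = "strain",
                  title = sprintf("Pearson r = %.3f", object$pearson_r)) +
    ggplot2::theme_minimal()
}

#' Plot per-strain SSR shares
#'
#' @param object A [fit_summary()] result.
#' @return A ggplot bar chart of each strain's contribution to total SSR.
#' @export
plot_ssr_shares <- function(object) {
  ggplot2::ggplot(object$per_strain,
                  ggplot2::aes(x = .data$strain_id, y = .data$share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "share of total SSR") +
    ggplot2::theme_minimal()
}

#' Plot an MFA flux distribution with confidence intervals
#'
#' @param object A tibble from [confidence_intervals()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mfa_fit
#' @export
autoplot.mfa_fit <- function(object, ...) {
  ggplot2::ggplot(object$fluxes,
                  ggplot2::aes(x = stats::reorder(.data$reaction_id, .data$flux),
                               y = .data$flux)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$flux - .data$sd,
                                          ymax = .data$flux + .data$sd)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "flux (mmol/100 mmol uptake)") +
    ggplot2::theme_minimal()
}
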