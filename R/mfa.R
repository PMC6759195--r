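nullspace_basis <- function(S, tol = 1e-10) {
  if (nrow(S) == 0) return(diag(ncol(S)))
  sv <- svd(S, nu = 0, nv = ncol(S))
  r <- sum(sv$d > tol * max(sv$d, 1))
  if (r == ncol(S)) return(matrix(0, ncol(S), 0))
  sv$v[, seq(r + 1, ncol(S)), drop = FALSE]
}

mfa_residual_fn <- function(ctx) {
  force(ctx)
  function(par) {
    nu <- ncol(ctx$N)
    u <- par[seq_len(nu)]
    v <- as.numeric(ctx$N %*% u)
    names(v) <- ctx$rxn_ids
    exch <- if (ctx$n_exch) exp(par[nu + seq_len(ctx$n_exch)]) else numeric()
    ex_v <- numeric(length(v))
    if (ctx$n_exch) ex_v[match(ctx$exch_ids, ctx$rxn_ids)] <- exch
    fl <- list(reaction_id = ctx$rxn_ids, flux = v, exch = ex_v)
    r_mid <- tryCatch({
      sim <- simulate_mids(ctx$net, fl, ctx$tracer)
      (sim$value[ctx$mid_idx] - ctx$mids$value) / ctx$mids$sd
    }, error = function(e) rep(1e3, ctx$n_mid))
    r_rate <- if (nrow(ctx$constraints)) {
      (v[ctx$constraints$reaction_id] - ctx$constraints$value) / ctx$constraints$sd
    } else numeric()
    pen <- c(
      pmax(0, -v[ctx$irrev_ids]) * 100,
      if (ctx$n_exch) pmax(0, par[nu + seq_len(ctx$n_exch)] - log(ctx$exch_hi)) * 100,
      if (ctx$n_exch) pmax(0, log(ctx$exch_lo) - par[nu + seq_len(ctx$n_exch)]) * 100
    )
    c(r_mid, r_rate, pen)
  }
}

mfa_meas_ssr <- function(res, ctx) sum(res[seq_len(ctx$n_mid + nrow(ctx$constraints))]^2)

#' Fit intracellular fluxes to labeling data (13C-MFA)
#'
#' Variance-weighted least-squares estimation of a steady-state flux
#' distribution from measured fragment mass isotopomer distributions and
#' measured rates. Net fluxes are parameterized on a null-space basis of the
#' balanced stoichiometric matrix; reversible reactions additionally carry a
#' log-parameterized exchange flux. Randomly initialized multi-starts are
#' performed and the best solution is accepted only if at least half of the
#' starts converge to it (within `max(0.1, 1%)` on every net flux).
#'
#' @param model A [metabolic_model()].
#' @param mids Measured MIDs: tibble `fragment_id`, `mass_shift`, `value`, `sd`.
#' @param fragments Fragment definitions (see [build_emu_network()]).
#' @param tracer A [tracer_spec()].
#' @param constraints Measured rates: tibble `reaction_id`, `value`, `sd`
#'   (typically substrate uptake normalized to 100 flux units, growth,
#'   secretion).
#' @param n_starts Number of random multi-starts.
#' @param seed Base random seed; start `i` uses `seed + i`.
#' @param u_range Half-width of the uniform initialization box for free
#'   fluxes.
#' @param exch_bounds Bounds for exchange fluxes of reversible reactions.
#' @param net Optional pre-built [build_emu_network()].
#' @return Object of class `mfa_fit`: fitted flux tibble (`flux`, `exch`,
#'   linearized `sd`), `ssr`, `dof`, `n_starts`, `convergence_fraction`,
#'   `accepted` flag, and internals reused by [confidence_intervals()].
#' @export
fit_fluxes <- function(model, mids, fragments, tracer, constraints,
                       n_starts = 100, seed = 1, u_range = 150,
                       exch_bounds = c(1e-6, 100), net = NULL) {
  if (is.null(net)) net <- build_emu_network(model, fragments)
  S <- stoichiometric_matrix(model, balanced_only = TRUE)
  N <- nullspace_basis(S)
  if (!ncol(N)) abort("model has no degrees of freedom: null space is empty")
  mids <- as_tibble(mids)
  constraints <- as_tibble(constraints %||% tibble(reaction_id = character(),
                                                  value = double(), sd = double()))
  rxn <- model$reactions
  frag_len <- vapply(strsplit(net$fragments$atoms, ","), length, integer(1))
  template <- paste(rep(net$fragments$fragment_id, frag_len + 1),
                    unlist(lapply(frag_len, function(n) 0:n)))
  mid_idx <- match(paste(mids$fragment_id, mids$mass_shift), template)
  if (anyNA(mid_idx)) {
    abort("measured MIDs reference fragments/mass shifts not in the EMU network")
  }
  ctx <- list(
    mid_idx = mid_idx,
    N = N, rxn_ids = rxn$id,
    irrev_ids = rxn$id[!rxn$reversible],
    exch_ids = rxn$id[rxn$reversible],
    n_exch = sum(rxn$reversible),
    exch_lo = exch_bounds[1], exch_hi = exch_bounds[2],
    net = net, tracer = tracer, mids = mids, constraints = constraints,
    n_mid = nrow(mids)
  )
  fn <- mfa_residual_fn(ctx)
  npar <- ncol(N) + ctx$n_exch

  starts <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    set.seed(seed + i)
    p0 <- c(runif(ncol(N), -u_range, u_range),
            runif(ctx$n_exch, log(ctx$exch_lo), log(ctx$exch_hi)))
    fitted <- tryCatch(
      minpack.lm::nls.lm(p0, fn = fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fitted)) { starts[[i]] <- NULL; next }
    res <- fn(fitted$par)
    starts[[i]] <- list(par = fitted$par, ssr = mfa_meas_ssr(res, ctx),
                        info = fitted$info,
                        converged = fitted$info %in% 1:4 && all(is.finite(res)))
  }
  ok <- which(map_lgl(starts, function(s) !is.null(s) && s$converged))
  if (!length(ok)) abort("no MFA start converged")
  ssrs <- map_dbl(starts[ok], "ssr")
  best <- starts[[ok[which.min(ssrs)]]]
  v_of <- function(par) as.numeric(ctx$N %*% par[seq_len(ncol(N))])
  v_best <- v_of(best$par)
  same <- map_lgl(starts, function(s) {
    if (is.null(s) || !s$converged) return(FALSE)
    all(abs(v_of(s$par) - v_best) <= pmax(0.1, 0.01 * abs(v_best)))
  })
  convergence_fraction <- mean(same)

  # linearized flux SDs from the measurement Jacobian at the optimum
  nmeas <- ctx$n_mid + nrow(constraints)
  J <- numeric_jacobian(function(p) fn(p)[seq_len(nmeas)], best$par)
  JtJ <- crossprod(J)
  cov_par <- tryCatch(solve(JtJ), error = function(e) MASS::ginv(JtJ))
  cov_v <- ctx$N %*% cov_par[seq_len(ncol(N)), seq_len(ncol(N)), drop = FALSE] %*% t(ctx$N)
  sd_v <- sqrt(pmax(diag(cov_v), 0))

  exch <- rep(0, length(ctx$rxn_ids))
  if (ctx$n_exch) {
    exch[match(ctx$exch_ids, ctx$rxn_ids)] <- exp(best$par[ncol(N) + seq_len(ctx$n_exch)])
  }
  fluxes <- tibble(reaction_id = ctx$rxn_ids, flux = v_best, exch = exch, sd = sd_v)

  structure(list(
    fluxes = fluxes,
    ssr = best$ssr,
    dof = nmeas - npar,
    n_starts = n_starts,
    convergence_fraction = convergence_fraction,
    accepted = convergence_fraction >= 0.5,
    par = best$par,
    start_ssr = map_dbl(starts[ok], "ssr"),
    ctx = ctx
  ), class = "mfa_fit")
}

#' @export
print.mfa_fit <- function(x, ...) {
  cat("<mfa_fit> SSR ", signif(x$ssr, 4), " (dof ", x$dof, "), ",
      round(100 * x$convergence_fraction), "% of ", x$n_starts,
      " starts at best solution; ",
      if (x$accepted) "accepted" else "NOT accepted", "\n", sep = "")
  invisible(x)
}

numeric_jacobian <- function(f, x, rel_step = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- rel_step * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

profile_ssr <- function(fit, rid, t, warm) {
  ctx <- fit$ctx
  N <- ctx$N
  j <- match(rid, ctx$rxn_ids)
  a <- N[j, ]
  p <- which.max(abs(a))
  fn_full <- mfa_residual_fn(ctx)
  nu <- ncol(N)
  embed <- function(q) {
    # q: free params without u_p; reconstruct u_p from the pinned flux value
    u <- numeric(nu)
    u[-p] <- q[seq_len(nu - 1)]
    u[p] <- (t - sum(a[-p] * u[-p])) / a[p]
    c(u, q[-seq_len(nu - 1)])
  }
  q0 <- c(warm[seq_len(nu)][-p], warm[-seq_len(nu)])
  fitted <- tryCatch(
    minpack.lm::nls.lm(q0, fn = function(q) fn_full(embed(q)),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 400, ftol = 1e-13, ptol = 1e-13)),
    error = function(e) NULL)
  if (is.null(fitted)) return(list(ssr = Inf, par = warm))
  par <- embed(fitted$par)
  # include the feasibility penalties: a profile point that can only "fit" by
  # driving an irreversible flux negative is outside the confidence region
  list(ssr = sum(fn_full(par)^2), par = par)
}

#' Profile-likelihood confidence intervals for fitted fluxes
#'
#' For each reaction, finds the smallest and largest flux value whose profile
#' SSR (all other free fluxes re-optimized) stays below `SSR* + chi^2_1(1 -
#' alpha)`; with the default `alpha = 0.05` the threshold increment is 3.84.
#' Structurally unidentifiable fluxes run to `bound` and are flagged.
#'
#' @param fit An accepted [fit_fluxes()] result.
#' @param reactions Reactions to profile (default: all).
#' @param alpha Significance level.
#' @param bound Search limit on |flux|.
#' @param tol Absolute tolerance on the reported interval endpoints.
#' @return Tibble `reaction_id`, `flux`, `ci_lo`, `ci_hi`, `lo_at_bound`,
#'   `hi_at_bound`.
#' @export
confidence_intervals <- function(fit, reactions = NULL, alpha = 0.05,
                                 bound = 1000, tol = 1e-3) {
  stopifnot(inherits(fit, "mfa_fit"))
  reactions <- reactions %||% fit$fluxes$reaction_id
  thresh <- fit$ssr + qchisq(1 - alpha, 1)
  out <- list()
  for (rid in reactions) {
    j <- match(rid, fit$ctx$rxn_ids)
    v0 <- fit$fluxes$flux[j]
    a <- fit$ctx$N[j, ]
    if (max(abs(a)) < 1e-12) {
      out[[rid]] <- tibble(reaction_id = rid, flux = v0, ci_lo = v0, ci_hi = v0,
                           lo_at_bound = FALSE, hi_at_bound = FALSE)
      next
    }
    one_side <- function(dir) {
      step <- max(0.5, 0.1 * abs(v0))
      t_in <- v0
      warm <- fit$par
      repeat {
        t_try <- t_in + dir * step
        if (abs(t_try) > bound) return(list(t = dir * bound, at_bound = TRUE))
        pr <- profile_ssr(fit, rid, t_try, warm)
        if (pr$ssr <= thresh) {
          t_in <- t_try; warm <- pr$par; step <- step * 1.7
        } else break
      }
      t_out <- t_try
      while (abs(t_out - t_in) > tol) {
        t_mid <- (t_in + t_out) / 2
        pr <- profile_ssr(fit, rid, t_mid, warm)
        if (pr$ssr <= thresh) { t_in <- t_mid; warm <- pr$par } else t_out <- t_mid
      }
      list(t = t_in, at_bound = FALSE)
    }
    lo <- tryCatch(one_side(-1), error = function(e) list(t = NA_real_, at_bound = NA))
    hi <- tryCatch(one_side(+1), error = function(e) list(t = NA_real_, at_bound = NA))
    out[[rid]] <- tibble(reaction_id = rid, flux = v0,
                         ci_lo = lo$t, ci_hi = hi$t,
                         lo_at_bound = lo$at_bound, hi_at_bound = hi$at_bound)
  }
  bind_rows(out)
}

#' Project a flux distribution onto another network
#'
#' Finds a steady-state flux distribution on the target network that minimizes
#' the total violation (sum of absolute excursions) of the supplied 95%
#' confidence intervals, solved as a linear program with slack variables.
#'
#' @param source_ci Tibble `reaction_id`, `ci_lo`, `ci_hi` (intervals
#'   elucidated on the source network).
#' @param target A [metabolic_model()] on which steady state must hold.
#' @param map Optional tibble `source_id`, `target_id`; defaults to matching
#'   reaction ids.
#' @param bound Box bound on |flux|.
#' @return List of class `flux_projection`: `fluxes` tibble and
#'   `total_violation` (flux units).
#' @export
project_fluxes <- function(source_ci, target, map = NULL, bound = 1000) {
  source_ci <- as_tibble(source_ci)
  if (is.null(map)) {
    shared <- intersect(source_ci$reaction_id, target$reactions$id)
    map <- tibble(source_id = shared, target_id = shared)
  }
  ci <- source_ci |>
    inner_join(map, by = c(reaction_id = "source_id"))
  S <- stoichiometric_matrix(target, balanced_only = TRUE)
  rxn <- target$reactions
  n <- nrow(rxn)
  lb <- ifelse(rxn$reversible, -bound, 0)
  m <- nrow(ci)
  # variables: x = v - lb (n), s_hi (m), s_lo (m); all >= 0
  cc <- c(rep(0, n), rep(1, 2 * m))
  Aeq <- cbind(S, matrix(0, nrow(S), 2 * m))
  beq <- as.numeric(-S %*% lb)
  jmap <- match(ci$target_id, rxn$id)
  A_hi <- matrix(0, m, n + 2 * m)
  A_lo <- matrix(0, m, n + 2 * m)
  for (i in seq_len(m)) {
    A_hi[i, jmap[i]] <- 1; A_hi[i, n + i] <- -1
    A_lo[i, jmap[i]] <- -1; A_lo[i, n + m + i] <- -1
  }
  b_hi <- ci$ci_hi - lb[jmap]
  b_lo <- -(ci$ci_lo - lb[jmap])
  A_ub <- cbind(diag(n), matrix(0, n, 2 * m))
  b_ub <- bound - lb
  sol <- pracma::linprog(cc, A = rbind(A_hi, A_lo, A_ub), b = c(b_hi, b_lo, b_ub),
                         Aeq = Aeq, beq = beq, maxiter = 1000)
  if (is.null(sol$x) || sol$errno < 0) {
    abort("flux projection LP failed: no steady-state solution found")
  }
  v <- sol$x[seq_len(n)] + lb
  structure(list(
    fluxes = tibble(reaction_id = rxn$id, flux = v),
    total_violation = sum(sol$x[n + seq_len(2 * m)])
  ), class = "flux_projection")
}
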