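test_that("ordered mechanisms have the expected steps, constants and complexes", {
  net <- decompose(uni_uni_model())
  expect_equal(nrow(net$steps), 2)                       # E+A = EA = E+P
  expect_equal(net$counts$n_elementary_constants, 4)
  expect_equal(nrow(net$complexes), 2)

  # one competitive inhibitor adds one dead-end binding step on free E
  net_i <- decompose(uni_uni_model("competitive"))
  expect_equal(nrow(net_i$steps), 3)
  expect_equal(net_i$counts$n_inhibitor_constants, 1)
  expect_equal(net_i$steps$complex_in[3], "R1:E")

  # uncompetitive binds the terminal substrate-bound complex
  net_u <- decompose(uni_uni_model("uncompetitive"))
  expect_equal(net_u$steps$complex_in[3], "R1:E:A")

  # noncompetitive binds both: two inhibitor constants per regulation
  net_n <- decompose(uni_uni_model("noncompetitive"))
  expect_equal(net_n$counts$n_inhibitor_constants, 2)

  # toy2: count from mechanism arithmetic (m + max(n,1) main steps per
  # reaction; the biomass sink is a 2-step uni mechanism)
  t2 <- decompose(toy2())
  regs <- toy2()$regulations
  expected_inh <- sum(ifelse(regs$mode == "noncompetitive", 2, 1))
  expect_equal(t2$counts$n_inhibitor_constants, expected_inh)
  expect_equal(t2$counts$n_elementary_constants, 2 * 20)
})

test_that("anchoring arithmetic follows from the flux split definitions", {
  # one-step view: v_net = 1, v_r = 0.5 -> forward flux 1.5; with e_free = 0.6
  # and unit concentrations k_f = 1.5 / 0.6 = 2.5
  net <- decompose(uni_uni_model())
  wt <- tibble::tibble(reaction_id = "R1", flux = 1)
  e <- c("R1:E" = 0.6, "R1:E:A" = 0.4)
  v_r <- c(0.5, 0.8); names(v_r) <- net$steps$step_id
  p <- anchor_wildtype(net, wt, e, v_r)
  expect_equal(p$k$k_f[1], 1.5 / 0.6)
  expect_equal(p$k$k_r[1], 0.5 / 0.4)
  expect_equal(p$k$k_f[2], 1.8 / 0.4)
  expect_equal(p$k$k_r[2], 0.8 / 0.6)

  # equilibrium reaction: v_net = 0, v_r = 2 -> v_fwd = 2
  wt0 <- tibble::tibble(reaction_id = "R1", flux = 0)
  v_r2 <- c(2, 2); names(v_r2) <- net$steps$step_id
  p0 <- anchor_wildtype(net, wt0, e, v_r2)
  expect_equal(p0$k$k_f[1] * e[["R1:E"]], 2)

  # reverse net flux larger than v_r makes a forward flux negative -> error
  wt_neg <- tibble::tibble(reaction_id = "R1", flux = -1)
  expect_error(anchor_wildtype(net, wt_neg, e, v_r), "positive forward flux")

  # complex fractions must sum to one per enzyme
  expect_error(anchor_wildtype(net, wt, c("R1:E" = 0.6, "R1:E:A" = 0.6), v_r),
               "sum to 1")
})

test_that("wild-type anchoring round-trips through the steady-state solver", {
  truth <- toy2_truth()
  ws <- steady_state(truth$net, truth$params)
  expect_equal(ws$status, "converged")
  j <- dplyr::inner_join(ws$fluxes, truth$wt_fluxes, by = "reaction_id",
                         suffix = c("_ss", "_wt"))
  expect_lt(max(abs(j$flux_ss - j$flux_wt)), 1e-8)
  expect_lt(max(abs(ws$concentrations$conc - 1)), 1e-10)
})

test_that("knockouts zero their reaction flux and conserve enzyme totals", {
  truth <- toy2_truth()
  ko <- steady_state(truth$net, truth$params, enzyme_levels = c(GLY = 0))
  expect_equal(ko$status, "converged")
  expect_equal(ko$fluxes$flux[ko$fluxes$reaction_id == "GLY"], 0)
  sums <- ko$complex_fractions |>
    dplyr::group_by(enzyme_id) |>
    dplyr::summarise(s = sum(fraction))
  expect_lt(max(abs(sums$s[sums$enzyme_id != "GLY"] - 1)), 1e-9)
  expect_equal(sums$s[sums$enzyme_id == "GLY"], 0)
})

test_that("iterative solver matches long-time stiff ODE integration", {
  truth <- toy2_truth()
  for (ko in c("GLY", "CLV", "PT")) {
    lev <- setNames(0, ko)
    a <- steady_state(truth$net, truth$params, enzyme_levels = lev, tol = 1e-11)
    b <- steady_state_ode(truth$net, truth$params, enzyme_levels = lev)
    expect_equal(a$status, "converged")
    expect_equal(b$status, "converged")
    jf <- dplyr::inner_join(a$fluxes, b$fluxes, by = "reaction_id")
    jc <- dplyr::inner_join(a$concentrations, b$concentrations,
                            by = "metabolite_id")
    expect_lt(max(abs(jf$flux.x - jf$flux.y) / pmax(1, abs(jf$flux.y))), 1e-6)
    expect_lt(max(abs(jc$conc.x - jc$conc.y) / pmax(1, abs(jc$conc.y))), 1e-6)
  }
})

test_that("analytic balance Jacobian agrees with finite differences", {
  truth <- toy2_truth()
  cmp <- kfitr:::compile_kinetics(truth$net, truth$params, c(GLY = 0))
  nb <- cmp$nbal
  set.seed(5)
  c0 <- setNames(exp(runif(nb, -1, 1)), cmp$mets[seq_len(nb)])
  rj <- kfitr:::metabolite_residual_jac(cmp, c0)
  Jfd <- matrix(0, nb, nb)
  for (j in seq_len(nb)) {
    h <- 1e-6 * max(1, abs(c0[j]))
    cp <- c0; cp[j] <- c0[j] + h
    cm <- c0; cm[j] <- c0[j] - h
    Jfd[, j] <- (kfitr:::metabolite_residual(cmp, cp)$g -
                   kfitr:::metabolite_residual(cmp, cm)$g) / (2 * h)
  }
  expect_lt(max(abs(rj$Jg - Jfd)) / max(abs(Jfd)), 1e-6)
  expect_equal(rj$g, kfitr:::metabolite_residual(cmp, c0)$g, tolerance = 1e-12)
})

test_that("stability verdicts match the sign of the analytic 1D derivative", {
  # substrate uptake feeding a sink whose enzyme is sequestered by
  # uncompetitive self-inhibition: consumption v(A) is non-monotone, giving a
  # stable low-A root and an unstable high-A root of supply - v(A) = 0
  mets <- tibble::tibble(id = c("Aext", "A"), carbon_count = c(1L, 1L),
                         is_extracellular = c(TRUE, FALSE))
  rxns <- tibble::tibble(id = c("UPT", "SNK"), reversible = FALSE,
                         is_biomass_sink = c(FALSE, TRUE))
  st <- tibble::tibble(reaction_id = c("UPT", "UPT", "SNK"),
                       metabolite_id = c("Aext", "A", "A"),
                       coef = c(-1, 1, -1))
  regs <- tibble::tibble(reaction_id = "SNK", inhibitor_id = "A",
                         mode = "uncompetitive")
  m <- metabolic_model(mets, rxns, st, regulations = regs,
                       uptake_reaction = "UPT")
  net <- decompose(m)
  # UPT: E+Aext=EA=E+A (2 steps); SNK: E+A=EA=E plus EA+A=EAI (3 steps)
  k <- tibble::tibble(step_id = net$steps$step_id,
                      k_f = c(1.0, 10, 40, 10, 30),
                      k_r = c(0.1, 0.001, 1, 0.01, 1))
  params <- structure(list(k = k), class = "kinetic_params")

  cmp <- kfitr:::compile_kinetics(net, params)
  g_of <- function(a) kfitr:::metabolite_residual(cmp, c(A = a))$g
  # bracket the roots of the 1D balance and find them by bisection
  roots <- c()
  grid <- exp(seq(log(1e-3), log(1e4), length.out = 400))
  gv <- vapply(grid, g_of, numeric(1))
  sgn <- sign(gv)
  idx <- which(diff(sgn) != 0)
  for (i in idx) {
    lo <- grid[i]; hi <- grid[i + 1]
    for (k2 in 1:80) {
      mid <- sqrt(lo * hi)
      if (sign(g_of(mid)) == sign(g_of(lo))) lo <- mid else hi <- mid
    }
    roots <- c(roots, sqrt(lo * hi))
  }
  skip_if(length(roots) < 2, "parameter set lost its bistability")
  verdicts <- logical(); slopes <- numeric()
  for (a in roots) {
    st0 <- steady_state(net, params, c0 = c(A = a), newton_gate = Inf)
    expect_equal(st0$status, "converged")
    sc <- stability_check(net, params, st0)
    verdicts <- c(verdicts, sc$stable)
    h <- 1e-6 * a
    slopes <- c(slopes, (g_of(a + h) - g_of(a - h)) / (2 * h))
  }
  # reduced-system slope sign must agree with the full linearization verdict
  expect_equal(verdicts, slopes < 0)
  expect_true(any(verdicts) && !all(verdicts))
})

test_that("conservation nullspace eigenvalues are excluded from the verdict", {
  truth <- toy2_truth()
  ws <- steady_state(truth$net, truth$params)
  sc <- stability_check(truth$net, truth$params, ws)
  expect_true(sc$stable)
  expect_lt(Re(sc$leading_eigenvalue), 0)
})
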