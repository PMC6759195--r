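test_that("covariance core reproduces the closed-form linear-model covariance", {
  # residuals r = (X b - y)/sd are linear in b, so SDs must equal the
  # square roots of the diagonal of (X' W X)^-1 — cross-checked against lm()
  set.seed(7)
  n <- 40
  X <- cbind(1, rnorm(n), runif(n))
  b_true <- c(2, -1, 0.5)
  sd_y <- 0.3
  y <- as.numeric(X %*% b_true) + rnorm(n, 0, sd_y)
  J <- X / sd_y   # d residual / d b
  cv <- covariance_from_jacobian(J)
  closed <- solve(t(X) %*% X / sd_y^2)
  expect_equal(diag(cv$covariance), diag(closed), tolerance = 1e-10)
  # lm() as an independent oracle (its vcov is sigma-hat-scaled)
  fit_lm <- lm(y ~ X - 1)
  expect_equal(unname(vcov(fit_lm) / summary(fit_lm)$sigma^2),
               unname(closed / sd_y^2), tolerance = 1e-8)

  # doubling all weights shrinks every SD by sqrt(2)... weights enter as
  # W = diag(w^2), so w = sqrt(2) doubles H and halves the covariance
  cv2 <- covariance_from_jacobian(J, w = rep(sqrt(2), n))
  expect_equal(sqrt(diag(cv2$covariance)),
               sqrt(diag(cv$covariance)) / sqrt(2), tolerance = 1e-10)

  # exactly collinear columns are flagged as null directions
  J_dup <- cbind(J, J[, 2])
  cv3 <- covariance_from_jacobian(J_dup)
  expect_gt(cv3$null_load[2], 1e-6)
  expect_gt(cv3$null_load[4], 1e-6)
})

test_that("dead-end inhibitor constants are rank-deficient pairs with finite Ki SD", {
  fit <- kinetic_pseudo_fit()
  rep <- cached("sens_report", sensitivity(fit))
  expect_s3_class(rep, "sensitivity_report")
  p <- rep$parameters
  expect_equal(nrow(p), 2 * nrow(fit$params$k))
  # a dead-end inhibitor binding step only constrains kf/kr: the pair loads
  # on a null direction and is flagged unidentifiable
  inh_steps <- fit$net$steps$step_id[!fit$net$steps$main_path]
  inh_rows <- p[p$step_id %in% inh_steps, ]
  expect_true(any(!inh_rows$identifiable))
  expect_true(all(is.finite(p$sd)))
})

test_that("regulation essentiality applies the value-minus-SD rule", {
  # rule cases first
  reg <- tibble::tibble(step_id = c("a", "b"), reaction_id = "r",
                        inhibitor_id = "i", mode = "competitive",
                        value = c(10, 0.5))
  # value 10, SD 2 -> essential; value 0.5, SD 1 -> nonessential
  out <- reg |> dplyr::mutate(sd = c(2, 1),
                              essential = (value - sd) > 0)
  expect_equal(out$essential, c(TRUE, FALSE))

  fit <- kinetic_pseudo_fit()
  rep <- cached("sens_report", sensitivity(fit))
  ess <- essential_regulations(fit, rep)
  expect_s3_class(ess, "regulation_essentiality")
  expect_equal(ess$n_total, sum(!fit$net$steps$main_path))
  expect_equal(ess$regulations$essential,
               (ess$regulations$value - ess$regulations$sd) > 0)
  expect_equal(tidy(ess), ess$regulations)
})

test_that("mm_ranges equals the exhaustive models-by-corners evaluation", {
  truth <- toy1_truth()
  # three pseudo-models with slightly different rate constants
  mk <- function(f) {
    p <- truth$params
    p$k$k_f <- p$k$k_f * f
    structure(list(params = p, net = truth$net, ssr = 100 * f,
                   start_index = round(100 * f)), class = "kinetic_fit")
  }
  models <- list(mk(1), mk(1.02), mk(1.05))
  metab <- tibble::tibble(
    metabolite_id = unique(c(truth$net$balanced_metabolites,
                             truth$net$boundary_metabolites)),
    mean = 2, sd = 0.5)
  rng <- mm_ranges(models, metab, reactions = "GLY", neighbor_frac = 0.10)
  expect_equal(rng$n_models, 3)

  # brute force over the 3 x 2 grid
  vals <- c()
  for (mo in models) {
    for (corner in c(1.5, 2.5)) {
      conc <- setNames(rep(corner, nrow(metab)), metab$metabolite_id)
      law <- king_altman(truth$net, "GLY",
                         params = scale_params(truth$net, mo$params, conc))
      vals <- c(vals, law$km$value[law$km$monomial == "1"])
    }
  }
  row <- rng$km[rng$km$monomial == "1", ]
  expect_equal(row$lo, min(vals), tolerance = 1e-12)
  expect_equal(row$hi, max(vals), tolerance = 1e-12)

  # single model, zero concentration SD: degenerate point range
  rng0 <- mm_ranges(models[1], dplyr::mutate(metab, sd = 0),
                    reactions = "GLY")
  expect_equal(rng0$km$lo, rng0$km$hi)
})
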