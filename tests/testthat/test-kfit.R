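test_that("weighting SD floor follows max(1.0, 0.05|v|, SD_MFA)", {
  fl <- tibble::tibble(
    strain_id = c("WT", "m1", "m1", "m1"),
    reaction_id = c("UPT", "r1", "r2", "r3"),
    flux = c(100, 100, 2, 0.1),
    sd = c(0, 0.5, 3, 0.01))
  up <- tibble::tibble(strain_id = c("WT", "m1"), uptake = c(10, 10))
  tr <- prepare_training(fl, up, wt_strain = "WT")
  sds <- setNames(tr$targets$sd, tr$targets$reaction_id)
  expect_equal(sds[["r1"]], 5.0)   # 0.05 * 100 dominates
  expect_equal(sds[["r2"]], 3.0)   # MFA SD dominates
  expect_equal(sds[["r3"]], 1.0)   # floor
})

test_that("uptake-ratio scaling puts mutants on the wild-type basis", {
  fl <- tibble::tibble(
    strain_id = c("WT", "m1"), reaction_id = c("UPT", "UPT"),
    flux = c(100, 100), sd = 0)
  up <- tibble::tibble(strain_id = c("WT", "m1"), uptake = c(8, 6))
  tr <- prepare_training(fl, up, wt_strain = "WT")
  expect_equal(tr$targets$flux, 100 * 6 / 8)
  expect_error(prepare_training(fl, up[1, ], wt_strain = "WT"),
               "missing absolute uptake")
})

test_that("excluded reactions are dropped from the residual set", {
  fl <- tibble::tibble(strain_id = c("WT", "m1", "m1"),
                       reaction_id = c("UPT", "UPT", "PFK"),
                       flux = c(100, 90, 10), sd = 0)
  up <- tibble::tibble(strain_id = c("WT", "m1"), uptake = c(1, 1))
  tr <- prepare_training(fl, up, wt_strain = "WT", exclude = "PFK")
  expect_false("PFK" %in% tr$targets$reaction_id)
})

test_that("SSR is the variance-weighted residual sum and is order-invariant", {
  tr <- structure(list(targets = tibble::tibble(
    strain_id = c("a", "a", "b"), reaction_id = c("r1", "r2", "r1"),
    flux = c(10, 5, 8), sd = c(1, 2, 1))), class = "kfit_training")
  pred <- tibble::tibble(strain_id = c("a", "a", "b"),
                         reaction_id = c("r1", "r2", "r1"),
                         flux = c(10, 5, 8))
  expect_equal(compute_ssr(pred, tr)$ssr, 0)
  pred$flux <- c(11, 5, 8)   # one flux off by exactly 1 SD
  expect_equal(compute_ssr(pred, tr)$ssr, 1)
  # reordering rows changes nothing
  expect_equal(compute_ssr(pred[c(3, 1, 2), ], tr)$ssr, 1)
})

test_that("model acceptance needs a 10% SSR neighbor; recovery uses 0.05/flux", {
  mk <- function(ssr, fluxshift) {
    structure(list(
      ssr = ssr,
      strain_states = list(s1 = structure(list(
        fluxes = tibble::tibble(reaction_id = c("r1", "r2"),
                                flux = c(1, 2) + fluxshift)),
        class = "steady_state")),
      net = NULL, params = NULL), class = "kinetic_fit")
  }
  # 360 <= 1.1 * 338: accepted
  sel <- accept_models(list(mk(338, 0), mk(360, 0.1), mk(500, 3)))
  expect_true(sel$accepted)
  expect_equal(sel$neighbor_indices, 2L)
  # mean squared deviation 0.1^2 = 0.01 <= 0.05 counts as recovered; 3^2 not
  expect_equal(sel$recovery_rate, 2 / 3)
  # {100, 200}: no neighbor within 10%
  sel2 <- accept_models(list(mk(100, 0), mk(200, 1)))
  expect_false(sel2$accepted)
})

test_that("kfit recovers a noise-free synthetic training set", {
  truth <- toy1_truth()
  m <- toy1()
  train <- toy1_train()
  # noise-free fluxes satisfy steady state exactly
  S <- stoichiometric_matrix(m, balanced_only = TRUE)
  wt_v <- setNames(train$wt_fluxes$flux, train$wt_fluxes$reaction_id)
  expect_lt(max(abs(S[, names(wt_v)] %*% wt_v)), 1e-9)

  fits <- toy1_kfit()
  expect_s3_class(fits, "kfit_results")
  best <- fits[[1]]
  expect_true(best$converged)
  expect_true(all(diff(sapply(fits, function(f) f$ssr)) >= 0))
  # per-enzyme complex fractions of the best model sum to 1
  esum <- tapply(best$params$e[best$net$complexes$complex_id],
                 best$net$complexes$enzyme_id, sum)
  expect_lt(max(abs(esum - 1)), 1e-8)
  # the truth parameters themselves reproduce the data exactly
  sc <- compute_ssr(truth$strain_states, train)
  expect_lt(sc$ssr, 1e-12)
  # fit results are bit-reproducible for a fixed seed: re-running the kept
  # best start alone gives the identical parameter vector
  i0 <- best$start_index
  fits2 <- suppressWarnings(
    kfit(m, train, n_starts = 1, seed = 7 + i0 - 1, vr_range = c(1, 100),
         net = truth$net))
  expect_identical(fits2[[1]]$theta, best$theta)
})

test_that("cross-validation flags strains with unique phenotypes", {
  truth <- toy1_truth()
  m <- toy1()
  train <- toy1_train()
  expect_error(cross_validate(m, train, "nope", net = truth$net),
               "not in training set")
  # dCLV and dCND are phenotypic twins (both sever the cleavage route), so
  # holding one out leaves an equivalent strain in the training data and a
  # well-fitted CV model transfers to the held-out strain
  best <- toy1_kfit()[[1]]
  cv <- suppressWarnings(
    cross_validate(m, train, "dCLV", init_theta = best$theta, max_starts = 1,
                   seed = 11, net = truth$net))
  expect_s3_class(cv, "kfit_cv")
  expect_equal(cv$n_starts_used, 1)
  n_ho <- sum(train$targets$strain_id == "dCLV")
  # the warm-started refit fits its reduced training set to ~0, and because a
  # twin remains in training, the held-out strain is predicted to well under
  # one weighting SD per flux
  expect_lt(cv$fitted_ssr, 1e-6)
  expect_lt(cv$held_out_ssr / n_ho, 1.0)
})
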