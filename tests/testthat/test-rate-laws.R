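test_that("uni-uni closed forms: Km = (k-1 + k2)/k1, Vmax = k2 * Et", {
  net <- decompose(uni_uni_model())
  p <- manual_params(net, k_f = c(2, 5), k_r = c(3, 0))
  law <- king_altman(net, "R1", params = p, Et = 1.5)
  km <- law$km$value[law$km$monomial == "1"]
  expect_equal(km, (3 + 5) / 2)
  expect_equal(law$vmax_f, 5 * 1.5)
})

test_that("competitive inhibition multiplies Km by (1 + [I] ki/k-i), Vmax unchanged", {
  net <- decompose(uni_uni_model("competitive"))
  p <- manual_params(net, k_f = c(2, 5, 7), k_r = c(3, 0, 4))
  law <- king_altman(net, "R1", params = p, Et = 1.5)
  km0 <- km_effective(law, c(I = 0))
  km2 <- km_effective(law, c(I = 2))
  base <- (3 + 5) / 2
  expect_equal(km0$value[km0$monomial == "1"], base)
  expect_equal(km2$value[km2$monomial == "1"], base * (1 + 2 * 7 / 4))
  expect_equal(law$vmax_f, 5 * 1.5)
})

test_that("random reversible bi-bi laws match the enzyme-balance oracle", {
  mets <- tibble::tibble(id = c("A", "B", "P", "Q"), carbon_count = 1L,
                         is_extracellular = TRUE)
  rxns <- tibble::tibble(id = "R2", reversible = TRUE)
  st <- tibble::tibble(reaction_id = "R2",
                       metabolite_id = c("A", "B", "P", "Q"),
                       coef = c(-1, -1, 1, 1))
  m <- metabolic_model(mets, rxns, st)
  net <- decompose(m)
  set.seed(9)
  for (rep in 1:3) {
    p <- manual_params(net, k_f = runif(4, 0.5, 5), k_r = runif(4, 0.5, 5))
    law <- king_altman(net, "R2", params = p, Et = 2)
    cmp <- kfitr:::compile_kinetics(net, p)
    for (i in 1:20) {
      conc <- setNames(runif(4, 0.2, 3), c("A", "B", "P", "Q"))
      v_expr <- evaluate_rate(law, conc)
      cx <- setNames(rep(1, length(cmp$mets)), cmp$mets)
      cx[names(conc)] <- conc
      e <- kfitr:::solve_complexes(cmp, cx[cmp$mets]) * 2
      v_num <- kfitr:::reaction_fluxes_at(cmp, cx[cmp$mets], e)[["R2"]]
      expect_lt(abs(v_expr - v_num) / max(abs(v_num), 1e-12), 1e-8)
    }
  }
})

test_that("zero inhibitor concentration recovers the uninhibited expression", {
  net_i <- decompose(uni_uni_model("noncompetitive"))
  net_0 <- decompose(uni_uni_model())
  p_i <- manual_params(net_i, k_f = c(2, 5, 7, 9), k_r = c(3, 1, 4, 2))
  p_0 <- manual_params(net_0, k_f = c(2, 5), k_r = c(3, 1))
  law_i <- king_altman(net_i, "R1", params = p_i)
  law_0 <- king_altman(net_0, "R1", params = p_0)
  km_i <- km_effective(law_i, c(I = 0))
  km_0 <- km_effective(law_0)
  j <- dplyr::inner_join(km_i, km_0, by = "monomial")
  expect_equal(j$value.x, j$value.y, tolerance = 1e-12)
  for (a in c(0.3, 1, 4)) {
    expect_equal(evaluate_rate(law_i, c(A = a, P = 0.5, I = 0)),
                 evaluate_rate(law_0, c(A = a, P = 0.5)), tolerance = 1e-12)
  }
})

test_that("every toy mechanism's derived law matches its numeric rate", {
  truth <- toy2_truth()
  net <- truth$net
  params <- truth$params
  set.seed(21)
  for (rid in c("GLY", "CLV", "CND", "PSNK")) {
    law <- king_altman(net, rid, params = params)
    cmp <- kfitr:::compile_kinetics(net, params)
    species <- unique(c(law$substrates, law$products, law$inhibitors))
    for (i in 1:5) {
      conc <- setNames(runif(length(species), 0.3, 2), species)
      cx <- setNames(rep(1, length(cmp$mets)), cmp$mets)
      cx[names(conc)] <- conc
      e_all <- kfitr:::solve_complexes(cmp, cx[cmp$mets])
      v_num <- kfitr:::reaction_fluxes_at(cmp, cx[cmp$mets], e_all)[[rid]]
      expect_lt(abs(evaluate_rate(law, conc) - v_num) / max(abs(v_num), 1e-10),
                1e-8)
    }
  }
})
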