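#' Brute-force isotopomer reference simulation
#'
#' Independent reference for [simulate_mids()]: enumerates the full positional
#' isotopomer distribution (2^n labeling states) of every mapped metabolite
#' and solves the steady-state labeling balances by fixed-point iteration of
#' the per-metabolite pool equations (well-mixed pools, so condensing
#' substrates combine independently). Exponential in carbon count, intended
#' for fixture networks with at most ~6 carbons per metabolite.
#'
#' @inheritParams simulate_mids
#' @param model A [metabolic_model()] with atom mappings.
#' @param fragments Fragment tibble as in [build_emu_network()].
#' @param tol Fixed-point convergence tolerance (sup norm).
#' @param max_sweeps Iteration budget.
#' @return Tibble `fragment_id`, `mass_shift`, `value`.
#' @export
simulate_mids_isotopomer <- function(model, fluxes, tracer, fragments,
                                     tol = 1e-14, max_sweeps = 100000) {
  cc <- setNames(model$metabolites$carbon_count, model$metabolites$id)
  extr <- setNames(model$metabolites$is_extracellular, model$metabolites$id)
  instances <- atom_reaction_instances(model)
  fl <- directional_fluxes(fluxes)
  vf <- setNames(fl$v_f, fl$reaction_id)
  vb <- setNames(fl$v_b, fl$reaction_id)

  mets <- unique(model$atom_maps$metabolite_id)
  # state: per metabolite, vector over 2^n binary patterns (bit i = carbon i labeled)
  npat <- setNames(2^cc[mets], mets)
  state <- lapply(mets, function(m) {
    x <- numeric(npat[[m]]); x[1] <- 1; x
  })
  names(state) <- mets

  source_dist <- function(m) {
    x <- numeric(npat[[m]])
    tr <- tracer[tracer$metabolite_id == m, , drop = FALSE]
    if (!nrow(tr)) { x[1] <- 1; return(x) }
    for (i in seq_len(nrow(tr))) {
      bits <- as.integer(strsplit(tr$pattern[[i]], "")[[1]])
      id <- sum(bits * 2^(seq_along(bits) - 1)) + 1
      x[id] <- x[id] + tr$fraction[[i]]
    }
    x
  }
  for (m in mets) if (isTRUE(extr[[m]])) state[[m]] <- source_dist(m)

  # precompute, per balanced metabolite, its producing instances with flux and
  # the atom provenance: for each product pattern index, probability =
  # product over substrates of marginal prob of required sub-pattern.
  prods_of <- lapply(mets, function(m) list())
  names(prods_of) <- mets
  for (p in instances) {
    v <- if (p$dir == "f") vf[[p$reaction_id]] else vb[[p$reaction_id]]
    for (pi in which(p$prods$metabolite_id %in% mets)) {
      m <- p$prods$metabolite_id[[pi]]
      if (isTRUE(extr[[m]])) next
      letters_p <- strsplit(p$prods$atoms[[pi]], "")[[1]]
      contribs <- list()
      for (si in seq_len(nrow(p$subs))) {
        letters_s <- strsplit(p$subs$atoms[[si]], "")[[1]]
        # product positions drawn from this substrate, and source positions
        ppos <- which(letters_p %in% letters_s)
        if (!length(ppos)) next
        spos <- match(letters_p[ppos], letters_s)
        contribs[[length(contribs) + 1]] <-
          list(met = p$subs$metabolite_id[[si]], ppos = ppos, spos = spos)
      }
      prods_of[[m]][[length(prods_of[[m]]) + 1]] <-
        list(flux = v * p$weight, contribs = contribs, n = length(letters_p))
    }
  }

  pattern_bits <- lapply(sort(unique(cc[mets])), function(n) {
    if (n == 0) return(matrix(0L, 1, 0))
    do.call(rbind, lapply(0:(2^n - 1), function(k) as.integer(intToBits(k)[1:n])))
  })
  names(pattern_bits) <- as.character(sort(unique(cc[mets])))

  marginal <- function(x, n, positions) {
    # marginal distribution of `positions` (in order) from full pattern dist x
    bits <- pattern_bits[[as.character(n)]]
    k <- length(positions)
    out <- numeric(2^k)
    sub_id <- bits[, positions, drop = FALSE] %*% 2^(0:(k - 1)) + 1
    for (i in seq_along(x)) out[sub_id[i]] <- out[sub_id[i]] + x[i]
    out
  }

  balanced <- mets[!map_lgl(mets, function(m) isTRUE(extr[[m]]))]
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (m in balanced) {
      plist <- prods_of[[m]]
      if (!length(plist)) next
      total <- sum(map_dbl(plist, "flux"))
      if (total <= 0) next
      acc <- numeric(npat[[m]])
      for (p in plist) {
        if (p$flux == 0) next
        dist_m <- numeric(npat[[m]])
        dist_m[1] <- 1
        for (ct in p$contribs) {
          sub_marg <- marginal(state[[ct$met]], cc[[ct$met]], ct$spos)
          k <- length(ct$ppos)
          bits_k <- pattern_bits[[as.character(k)]]
          lift <- numeric(npat[[m]])
          ids <- bits_k %*% 2^(ct$ppos - 1) + 1
          for (j in seq_len(2^k)) lift[ids[j]] <- lift[ids[j]] + sub_marg[j]
          # combine independent contributions: "convolution" over disjoint bits
          dist_m <- combine_disjoint(dist_m, lift, npat[[m]])
        }
        acc <- acc + p$flux * dist_m
      }
      newx <- acc / total
      delta <- max(delta, max(abs(newx - state[[m]])))
      state[[m]] <- newx
    }
    if (delta < tol) break
  }
  if (delta >= tol) warn("isotopomer fixed point did not fully converge")

  fragments <- as_tibble(fragments)
  out <- list()
  for (i in seq_len(nrow(fragments))) {
    m <- fragments$metabolite_id[[i]]
    pos <- as.integer(strsplit(fragments$atoms[[i]], ",")[[1]])
    marg <- marginal(state[[m]], cc[[m]], pos)
    bits_k <- pattern_bits[[as.character(length(pos))]]
    shift <- rowSums(bits_k)
    mid <- numeric(length(pos) + 1)
    for (j in seq_along(marg)) mid[shift[j] + 1] <- mid[shift[j] + 1] + marg[j]
    out[[i]] <- tibble(fragment_id = fragments$fragment_id[[i]],
                       mass_shift = 0:length(pos), value = mid)
  }
  bind_rows(out)
}

# distribution of OR-combination of two independent pattern distributions with
# disjoint support bits
combine_disjoint <- function(a, b, n) {
  nz_a <- which(a != 0); nz_b <- which(b != 0)
  out <- numeric(n)
  for (i in nz_a) {
    ids <- bitwOr(i - 1L, nz_b - 1L) + 1L
    out[ids] <- out[ids] + a[i] * b[nz_b]
  }
  out
}
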