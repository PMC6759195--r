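emu_key <- function(metabolite_id, atoms) {
  paste0(metabolite_id, "[", paste(sort(unique(atoms)), collapse = ","), "]")
}

# Expand a model's atom mappings into directed mapped-reaction instances.
# Reversible reactions contribute a reverse instance with sides swapped; flux
# lookup then uses forward/backward fluxes (net split + exchange).
atom_reaction_instances <- function(model) {
  am <- model$atom_maps
  if (!nrow(am)) return(list())
  out <- list()
  rev_tbl <- setNames(model$reactions$reversible, model$reactions$id)
  for (rid in unique(am$reaction_id)) {
    for (mid in unique(am$mapping_id[am$reaction_id == rid])) {
      rows <- am[am$reaction_id == rid & am$mapping_id == mid, ]
      w <- rows$weight[[1]]
      subs <- rows[rows$role == "substrate", c("metabolite_id", "atoms")]
      prods <- rows[rows$role == "product", c("metabolite_id", "atoms")]
      out[[length(out) + 1]] <- list(reaction_id = rid, dir = "f", weight = w,
                                     subs = subs, prods = prods)
      if (isTRUE(rev_tbl[[rid]])) {
        out[[length(out) + 1]] <- list(reaction_id = rid, dir = "b", weight = w,
                                       subs = prods, prods = subs)
      }
    }
  }
  out
}

#' Build an EMU network
#'
#' Decomposes an atom-mapped metabolic network into the minimal set of
#' elementary metabolite units (EMUs) required to simulate the mass isotopomer
#' distributions of the requested fragments, following the standard
#' backward-tracing algorithm: starting from each measured fragment, every
#' producing mapped reaction contributes a source EMU (or a convolution of
#' source EMUs for condensation reactions), and the resulting balances are
#' blocked by EMU size so each block is a linear system given all smaller
#' blocks.
#'
#' Extracellular metabolites are treated as labeling sources (tracer inputs or
#' unlabeled) and are not expanded further.
#'
#' @param model A [metabolic_model()] with atom mappings.
#' @param fragments Tibble with columns `fragment_id`, `metabolite_id`,
#'   `atoms` (comma-separated 1-based carbon positions, e.g. `"1,2,3"`).
#' @return An object of class `emu_network`.
#' @export
build_emu_network <- function(model, fragments) {
  fragments <- as_tibble(fragments)
  cc <- setNames(model$metabolites$carbon_count, model$metabolites$id)
  extr <- setNames(model$metabolites$is_extracellular, model$metabolites$id)
  instances <- atom_reaction_instances(model)

  parse_atoms <- function(s) as.integer(strsplit(s, ",")[[1]])
  frag <- fragments |>
    mutate(atom_set = map(.data$atoms, parse_atoms))
  for (i in seq_len(nrow(frag))) {
    a <- frag$atom_set[[i]]
    m <- frag$metabolite_id[[i]]
    if (!m %in% names(cc)) abort(paste0("fragment metabolite not in model: ", m))
    if (length(a) == 0 || any(a < 1) || any(a > cc[[m]])) {
      abort(paste0("fragment ", frag$fragment_id[[i]],
                   ": atom positions outside 1..", cc[[m]], " of ", m))
    }
  }
  frag$key <- map2_chr_(frag$metabolite_id, frag$atom_set, emu_key)

  emus <- new.env(parent = emptyenv())
  productions <- list()
  queue <- unique(frag$key)
  key_info <- function(key) {
    m <- sub("\\[.*$", "", key)
    a <- as.integer(strsplit(sub("^.*\\[(.*)\\]$", "\\1", key), ",")[[1]])
    list(metabolite_id = m, atoms = a)
  }

  while (length(queue)) {
    key <- queue[[1]]; queue <- queue[-1]
    if (!is.null(emus[[key]])) next
    info <- key_info(key)
    is_source <- isTRUE(extr[[info$metabolite_id]])
    emus[[key]] <- list(metabolite_id = info$metabolite_id, atoms = info$atoms,
                        size = length(info$atoms), is_source = is_source)
    if (is_source) next
    produced <- FALSE
    for (p in instances) {
      prod_rows <- which(p$prods$metabolite_id == info$metabolite_id)
      for (pi in prod_rows) {
        letters_p <- strsplit(p$prods$atoms[[pi]], "")[[1]]
        want <- letters_p[info$atoms]
        srcs <- character()
        for (si in seq_len(nrow(p$subs))) {
          letters_s <- strsplit(p$subs$atoms[[si]], "")[[1]]
          pos <- which(letters_s %in% want)
          if (length(pos)) srcs <- c(srcs, emu_key(p$subs$metabolite_id[[si]], pos))
        }
        if (!length(srcs)) next  # atoms originate outside mapped carbon (not expected)
        produced <- TRUE
        productions[[length(productions) + 1]] <- list(
          target = key, reaction_id = p$reaction_id, dir = p$dir,
          weight = p$weight, sources = srcs)
        queue <- c(queue, srcs)
      }
    }
    if (!produced) {
      abort(paste0("EMU ", key, " has no producing mapped reaction and is not ",
                   "an extracellular source"))
    }
  }

  keys <- ls(emus)
  emu_tbl <- tibble(
    key = keys,
    metabolite_id = map_chr(keys, function(k) emus[[k]]$metabolite_id),
    size = map_dbl(keys, function(k) emus[[k]]$size),
    atoms = map(keys, function(k) emus[[k]]$atoms),
    is_source = map_lgl(keys, function(k) emus[[k]]$is_source)
  )

  out <- structure(
    list(emus = emu_tbl,
         productions = productions,
         fragments = frag |> select("fragment_id", "metabolite_id", "atoms", "key"),
         sizes = sort(unique(emu_tbl$size[!emu_tbl$is_source]))),
    class = "emu_network"
  )
  out$compiled <- compile_emu_network(out)
  out
}

# Integer-indexed form of the EMU balance systems, precomputed once so MID
# simulation inside fitting loops avoids any per-call bookkeeping.
compile_emu_network <- function(net) {
  keys <- net$emus$key
  kid <- setNames(seq_along(keys), keys)
  blocks <- list()
  for (s in net$sizes) {
    unknown <- which(net$emus$size == s & !net$emus$is_source)
    loc <- setNames(seq_along(unknown), keys[unknown])
    prods <- list()
    for (p in net$productions) {
      if (is.na(loc[p$target])) next
      src_ids <- unname(kid[p$sources])
      in_block <- length(src_ids) == 1 && !is.na(loc[p$sources])
      prods[[length(prods) + 1]] <- list(
        t_loc = unname(loc[p$target]),
        reaction_id = p$reaction_id,
        dir = p$dir,
        weight = p$weight,
        src_loc = if (in_block) unname(loc[p$sources]) else NA_integer_,
        src_ids = src_ids)
    }
    blocks[[as.character(s)]] <- list(size = s, unknown = unknown, prods = prods)
  }
  list(blocks = blocks, n_emu = length(keys),
       source_idx = which(net$emus$is_source),
       frag_idx = unname(kid[net$fragments$key]))
}

map2_chr_ <- function(x, y, f) vapply(seq_along(x), function(i) f(x[[i]], y[[i]]), character(1))

#' @export
print.emu_network <- function(x, ...) {
  cat("<emu_network> ", nrow(x$emus), " EMUs (",
      sum(x$emus$is_source), " sources), block sizes: ",
      paste(x$sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Define an isotope tracer
#'
#' @param metabolite_id Fed (extracellular) metabolite.
#' @param patterns Tibble with columns `fraction` (summing to 1) and `pattern`
#'   (one character per carbon, `"1"` for labeled). `[1,2-13C]` hexose at 100%
#'   is `tracer_spec("glc_ext", tibble(fraction = 1, pattern = "110000"))`.
#' @return Tibble with columns `metabolite_id`, `fraction`, `pattern`.
#' @export
tracer_spec <- function(metabolite_id, patterns) {
  patterns <- as_tibble(patterns)
  if (abs(sum(patterns$fraction) - 1) > 1e-9) abort("tracer fractions must sum to 1")
  tibble(metabolite_id = metabolite_id, fraction = patterns$fraction,
         pattern = patterns$pattern)
}

source_emu_mid <- function(tracer, metabolite_id, atoms) {
  n <- length(atoms)
  mid <- numeric(n + 1)
  tr <- tracer[tracer$metabolite_id == metabolite_id, , drop = FALSE]
  if (!nrow(tr)) { mid[1] <- 1; return(mid) }  # unlabeled source
  for (i in seq_len(nrow(tr))) {
    bits <- as.integer(strsplit(tr$pattern[[i]], "")[[1]])
    shift <- sum(bits[atoms])
    mid[shift + 1] <- mid[shift + 1] + tr$fraction[[i]]
  }
  mid
}

directional_fluxes <- function(fluxes) {
  ex <- if ("exch" %in% names(fluxes)) fluxes$exch else 0
  list(reaction_id = fluxes$reaction_id,
       v_f = pmax(fluxes$flux, 0) + ex,
       v_b = pmax(-fluxes$flux, 0) + ex)
}

#' Simulate mass isotopomer distributions
#'
#' Solves the cascaded EMU balance systems block-by-block (ascending EMU size)
#' for a steady-state flux distribution and tracer, and returns the mass
#' isotopomer distribution (MID) of every requested fragment. Condensation
#' contributions are discrete convolutions of the parent EMU MIDs. Reversible
#' reactions carry forward/backward fluxes `max(v,0)+exch` / `max(-v,0)+exch`.
#'
#' @param net An [build_emu_network()] result.
#' @param fluxes Tibble `reaction_id`, `flux`, optional `exch`.
#' @param tracer A [tracer_spec()] (rows may cover several fed metabolites).
#' @return Tibble `fragment_id`, `mass_shift`, `value`; each fragment's values
#'   are non-negative and sum to 1.
#' @export
simulate_mids <- function(net, fluxes, tracer) {
  fl <- directional_fluxes(fluxes)
  vf <- setNames(fl$v_f, fl$reaction_id)
  vb <- setNames(fl$v_b, fl$reaction_id)
  cmp <- net$compiled %||% compile_emu_network(net)

  mids <- vector("list", cmp$n_emu)
  for (i in cmp$source_idx) {
    row <- net$emus[i, ]
    mids[[i]] <- source_emu_mid(tracer, row$metabolite_id, row$atoms[[1]])
  }

  conv <- function(a, b) {
    n <- length(a) + length(b) - 1
    out <- numeric(n)
    for (i in seq_along(a)) {
      out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
    }
    out
  }

  for (bl in cmp$blocks) {
    s <- bl$size
    nu <- length(bl$unknown)
    M <- matrix(0, nu, nu)
    R <- matrix(0, nu, s + 1)
    for (p in bl$prods) {
      v <- (if (p$dir == "f") vf[[p$reaction_id]] else vb[[p$reaction_id]]) * p$weight
      u <- p$t_loc
      M[u, u] <- M[u, u] + v
      if (!is.na(p$src_loc)) {
        M[u, p$src_loc] <- M[u, p$src_loc] - v
      } else {
        x <- mids[[p$src_ids[1]]]
        if (length(p$src_ids) > 1) {
          for (k in p$src_ids[-1]) x <- conv(x, mids[[k]])
        }
        R[u, ] <- R[u, ] + v * x
      }
    }
    dg <- diag(M)
    if (nu == 1) dg <- M[1, 1]
    dead <- dg <= 1e-12
    if (any(dead)) {
      # a pool with no production carries no flux at steady state; if it is a
      # requested fragment its MID is undefined, otherwise it only feeds
      # zero-flux terms downstream and a placeholder is harmless
      if (any(bl$unknown[dead] %in% cmp$frag_idx)) {
        abort(paste0("singular EMU balance (no production flux) for ",
                     paste(net$emus$key[bl$unknown][dead], collapse = ", ")))
      }
      for (q in which(dead)) {
        M[q, ] <- 0; M[q, q] <- 1
        R[q, ] <- c(1, rep(0, s))
      }
    }
    X <- solve(M, R)
    if (nu == 1) X <- matrix(X, 1)
    for (q in seq_len(nu)) mids[[bl$unknown[q]]] <- X[q, ]
  }

  frag <- net$fragments
  vals <- lapply(cmp$frag_idx, function(i) mids[[i]])
  lens <- lengths(vals)
  tibble(fragment_id = rep(frag$fragment_id, lens),
         mass_shift = unlist(lapply(lens, function(n) seq_len(n) - 1L)),
         value = unlist(vals))
}
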