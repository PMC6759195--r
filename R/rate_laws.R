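# symbolic term: list(k = character vector of rate-constant names,
#                     conc = named integer vector of concentration exponents)
term_monomial <- function(conc) {
  if (!length(conc)) return("1")
  conc <- conc[order(names(conc))]
  paste(ifelse(conc == 1, names(conc), paste0(names(conc), "^", conc)),
        collapse = "*")
}

term_expr <- function(terms) {
  paste(vapply(terms, function(t) paste(sort(t$k), collapse = "*"), character(1)),
        collapse = " + ")
}

mul_term <- function(a, b) {
  conc <- c(a$conc, b$conc)
  if (length(conc)) conc <- tapply(conc, names(conc), sum)
  list(k = c(a$k, b$k), conc = as.integer(conc) |> setNames(names(conc)))
}

eval_terms <- function(terms, kval, conc) {
  if (!length(terms)) return(0)
  sum(vapply(terms, function(t) {
    prod(kval[t$k]) * (if (length(t$conc)) prod(conc[names(t$conc)]^t$conc) else 1)
  }, numeric(1)))
}

# enumerate spanning trees of an undirected multigraph given as edge list
spanning_trees <- function(n_nodes, edges_from, edges_to) {
  ne <- length(edges_from)
  need <- n_nodes - 1
  if (need == 0) return(list(integer(0)))
  combs <- utils::combn(ne, need, simplify = FALSE)
  keep <- list()
  for (cb in combs) {
    # union-find connectivity check, reject cycles
    parent <- seq_len(n_nodes)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    ok <- TRUE
    for (eidx in cb) {
      a <- find(edges_from[eidx]); b <- find(edges_to[eidx])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) keep[[length(keep) + 1]] <- cb
  }
  keep
}

#' Derive a Michaelis-Menten-form rate law by the King-Altman method
#'
#' Enumerates the directed spanning trees of a reaction's enzyme-complex
#' graph (inhibitor complexes included as nodes) to obtain the steady-state
#' complex abundances, and assembles the net rate law of the reaction as a
#' ratio of sums of kinetic terms. Each distinct term of the denominator is
#' reported as one Km parameter (normalized so that the all-substrates term
#' has coefficient 1), and the maximal forward rate Vmax is read off the
#' numerator with total enzyme `Et`.
#'
#' @param net An [decompose()] result.
#' @param reaction_id Reaction whose mechanism is derived.
#' @param params Optional [anchor_wildtype()] result supplying numeric rate
#'   constants (enables `value` columns and [evaluate_rate()]).
#' @param Et Total enzyme (scales Vmax).
#' @return Object of class `mm_rate_law`: symbolic numerator/denominator
#'   terms, `km` tibble (one row per distinct denominator term: `monomial`,
#'   `expression`, numeric `value` per unit of its concentration monomial),
#'   `vmax_f`/`vmax_r` (numeric when `params` given), and bookkeeping of
#'   substrate/product/inhibitor species.
#' @export
king_altman <- function(net, reaction_id, params = NULL, Et = 1) {
  st <- net$steps |> filter(.data$reaction_id == !!reaction_id)
  if (!nrow(st)) abort(paste0("unknown reaction: ", reaction_id))
  nodes <- unique(c(st$complex_in, st$complex_out))
  nid <- setNames(seq_along(nodes), nodes)
  # each step: forward edge (cin->cout) weight kf * [met_in]; reverse kr * [met_out]
  kf_name <- paste0("kf.", st$step_id)
  kr_name <- paste0("kr.", st$step_id)
  fwd_term <- lapply(seq_len(nrow(st)), function(i) {
    conc <- if (!is.na(st$met_in[i])) setNames(1L, st$met_in[i]) else
      setNames(integer(0), character(0))
    list(k = kf_name[i], conc = conc)
  })
  rev_term <- lapply(seq_len(nrow(st)), function(i) {
    conc <- if (!is.na(st$met_out[i])) setNames(1L, st$met_out[i]) else
      setNames(integer(0), character(0))
    list(k = kr_name[i], conc = conc)
  })

  comp <- rep(0L, length(nodes))
  # connectivity check
  reach <- 1L
  repeat {
    newr <- unique(c(reach,
                     nid[st$complex_out[nid[st$complex_in] %in% reach]],
                     nid[st$complex_in[nid[st$complex_out] %in% reach]]))
    if (length(newr) == length(reach)) break
    reach <- newr
  }
  if (length(reach) < length(nodes)) abort("disconnected enzyme-complex graph")

  trees <- spanning_trees(length(nodes), nid[st$complex_in], nid[st$complex_out])
  # directed trees toward each root
  T_terms <- vector("list", length(nodes))
  for (r in seq_along(nodes)) T_terms[[r]] <- list()
  for (tree in trees) {
    # orient each edge toward the root via BFS from root over tree adjacency
    adj <- lapply(seq_along(nodes), function(i) integer(0))
    for (eidx in tree) {
      a <- nid[[st$complex_in[eidx]]]; b <- nid[[st$complex_out[eidx]]]
      adj[[a]] <- c(adj[[a]], eidx); adj[[b]] <- c(adj[[b]], eidx)
    }
    for (r in seq_along(nodes)) {
      # parent pointers from root outward; edge direction = toward parent
      visited <- rep(FALSE, length(nodes)); visited[r] <- TRUE
      frontier <- r
      term <- list(k = character(0), conc = setNames(integer(0), character(0)))
      ok <- TRUE
      while (length(frontier)) {
        nxt <- integer(0)
        for (u in frontier) {
          for (eidx in adj[[u]]) {
            a <- nid[[st$complex_in[eidx]]]; b <- nid[[st$complex_out[eidx]]]
            other <- if (a == u) b else a
            if (visited[other]) next
            visited[other] <- TRUE
            nxt <- c(nxt, other)
            # edge must run other -> u
            w <- if (other == a && u == b) fwd_term[[eidx]] else rev_term[[eidx]]
            term <- mul_term(term, w)
          }
        }
        frontier <- nxt
      }
      if (ok) T_terms[[r]] <- c(T_terms[[r]], list(term))
    }
  }

  # output step: last main-path step of the mechanism
  main <- which(st$main_path)
  out_i <- main[length(main)]
  pre <- nid[[st$complex_in[out_i]]]
  post <- nid[[st$complex_out[out_i]]]
  num_f <- lapply(T_terms[[pre]], function(t) mul_term(t, fwd_term[[out_i]]))
  num_r <- lapply(T_terms[[post]], function(t) mul_term(t, rev_term[[out_i]]))
  den <- do.call(c, T_terms)

  substrates <- st$met_in[st$kind == "binding"]
  inhibitors <- unique(st$met_in[st$kind == "inhibitor_binding"])
  products <- st$met_out[!is.na(st$met_out) & st$main_path]
  mu_star <- table(substrates)
  mu_star_key <- term_monomial(setNames(as.integer(mu_star), names(mu_star)))

  den_keys <- vapply(den, function(t) term_monomial(t$conc), character(1))
  kval <- NULL
  if (!is.null(params)) {
    kval <- c(setNames(params$k$k_f, paste0("kf.", params$k$step_id)),
              setNames(params$k$k_r, paste0("kr.", params$k$step_id)))
  }
  unit_conc <- setNames(rep(1, length(unique(c(substrates, products, inhibitors)))),
                        unique(c(substrates, products, inhibitors)))
  sigma_star <- if (!is.null(kval))
    eval_terms(den[den_keys == mu_star_key], kval, unit_conc) else NA_real_

  km <- tibble(monomial = unique(den_keys)) |>
    mutate(
      expression = map_chr(.data$monomial, function(m)
        paste0("(", term_expr(den[den_keys == m]), ") / (",
               term_expr(den[den_keys == mu_star_key]), ")")),
      value = if (!is.null(kval))
        map_dbl(.data$monomial, function(m)
          eval_terms(den[den_keys == m], kval, unit_conc) / sigma_star)
      else NA_real_
    ) |>
    filter(.data$monomial != mu_star_key)

  num_f_keys <- vapply(num_f, function(t) term_monomial(t$conc), character(1))
  vmax_f <- if (!is.null(kval))
    Et * eval_terms(num_f[num_f_keys == mu_star_key], kval, unit_conc) / sigma_star
  else NA_real_
  mu_rev <- table(products)
  mu_rev_key <- term_monomial(setNames(as.integer(mu_rev), names(mu_rev)))
  num_r_keys <- vapply(num_r, function(t) term_monomial(t$conc), character(1))
  vmax_r <- if (!is.null(kval)) {
    sig_rev <- eval_terms(den[den_keys == mu_rev_key], kval, unit_conc)
    if (sig_rev > 0)
      Et * eval_terms(num_r[num_r_keys == mu_rev_key], kval, unit_conc) / sig_rev
    else NA_real_
  } else NA_real_

  structure(list(
    reaction_id = reaction_id,
    numerator_f = num_f, numerator_r = num_r, denominator = den,
    km = km, vmax_f = vmax_f, vmax_r = vmax_r,
    substrates = substrates, products = products, inhibitors = inhibitors,
    mu_star = mu_star_key,
    kval = kval, Et = Et
  ), class = "mm_rate_law")
}

#' @export
print.mm_rate_law <- function(x, ...) {
  cat("<mm_rate_law> ", x$reaction_id, ": ", nrow(x$km), " Km term(s)",
      if (!is.na(x$vmax_f)) paste0(", Vmax_f = ", signif(x$vmax_f, 5)), "\n",
      sep = "")
  invisible(x)
}

#' Evaluate a derived rate law at given concentrations
#'
#' @param law A [king_altman()] result built with numeric `params`.
#' @param conc Named concentration vector covering all substrates, products
#'   and inhibitors of the mechanism (missing species default to 1).
#' @return Net reaction rate (flux units).
#' @export
evaluate_rate <- function(law, conc = NULL) {
  if (is.null(law$kval)) abort("rate law has no numeric parameters")
  species <- unique(c(law$substrates, law$products, law$inhibitors))
  cv <- setNames(rep(1, length(species)), species)
  if (!is.null(conc)) cv[names(conc)] <- conc
  num <- eval_terms(law$numerator_f, law$kval, cv) -
    eval_terms(law$numerator_r, law$kval, cv)
  den <- eval_terms(law$denominator, law$kval, cv)
  law$Et * num / den
}

#' Effective Km terms at given inhibitor concentrations
#'
#' Groups the Km terms of a derived rate law by their substrate/product
#' monomial and substitutes numeric inhibitor concentrations, so that e.g. a
#' competitive dead-end inhibitor I multiplies the substrate-free Km term by
#' `(1 + [I] * ki / k-i)`.
#'
#' @param law A [king_altman()] result with numeric parameters.
#' @param inhibitor_conc Named vector of inhibitor concentrations (default:
#'   all 0, recovering the uninhibited expression).
#' @return Tibble `monomial` (inhibitor-free part), `value`.
#' @export
km_effective <- function(law, inhibitor_conc = NULL) {
  inh <- law$inhibitors
  ic <- setNames(rep(0, length(inh)), inh)
  if (!is.null(inhibitor_conc)) ic[names(inhibitor_conc)] <- inhibitor_conc
  if (!nrow(law$km)) return(tibble(monomial = character(), value = double()))
  parts <- lapply(seq_len(nrow(law$km)), function(i) {
    m <- law$km$monomial[i]
    # decompose monomial string back into factors
    if (m == "1") {
      bare <- character(0); exps <- integer(0)
    } else {
      f <- strsplit(m, "*", fixed = TRUE)[[1]]
      bare <- sub("\\^.*$", "", f)
      exps <- ifelse(grepl("\\^", f), as.integer(sub("^.*\\^", "", f)), 1L)
    }
    is_i <- bare %in% inh
    scale <- if (any(is_i)) prod(ic[bare[is_i]]^exps[is_i]) else 1
    rest <- setNames(exps[!is_i], bare[!is_i])
    tibble(monomial = term_monomial(rest), value = law$km$value[i] * scale)
  })
  bind_rows(parts) |>
    group_by(.data$monomial) |>
    summarise(value = sum(.data$value)) |>
    ungroup()
}

#' Rescale anchored rate constants to absolute concentration units
#'
#' The fitted model works on a wild-type-scaled concentration basis (all
#' pools = 1). Given absolute metabolite concentrations, this rescales each
#' rate constant so rate laws are expressed in absolute units:
#' `k_f' = k_f / c(bound metabolite)`, `k_r' = k_r / c(released metabolite)`.
#'
#' @param net An [decompose()] result.
#' @param params A [anchor_wildtype()] result.
#' @param conc Named absolute concentrations (missing species keep scale 1).
#' @return A rescaled `kinetic_params` object.
#' @export
scale_params <- function(net, params, conc) {
  st <- net$steps
  lookup <- function(m) {
    v <- unname(conc[m])
    ifelse(is.na(m) | is.na(v), 1, v)
  }
  k <- params$k
  k$k_f <- k$k_f / lookup(st$met_in)
  k$k_r <- k$k_r / lookup(st$met_out)
  out <- params
  out$k <- k
  out
}
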