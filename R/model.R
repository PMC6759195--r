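#' Construct a metabolic model
#'
#' Assembles a validated in-memory representation of a metabolic network:
#' metabolites with carbon counts, reactions with stoichiometry and atom
#' mappings, substrate-level regulations, and substrate binding / product
#' release orders used for elementary decomposition.
#'
#' All inputs are plain tibbles/data frames, mirroring the TSV sheet layout
#' read by [read_model()]:
#'
#' * `metabolites`: `id`, `carbon_count`, optional `is_extracellular`,
#'   `is_biomass_precursor`.
#' * `reactions`: `id`, optional `reversible`, `enzyme_id` (defaults to the
#'   reaction id), `excluded_from_fit`, `is_biomass_sink`, `is_uptake`.
#' * `stoichiometry`: long format `reaction_id`, `metabolite_id`, `coef`
#'   (substrates negative, products positive).
#' * `atom_maps`: `reaction_id`, `mapping_id`, `weight`, `role`
#'   (`"substrate"`/`"product"`), `metabolite_id`, `atoms` (lowercase letter
#'   string, one letter per carbon, e.g. `A(ab)+B(c)->C(abc)` is encoded as
#'   three rows with atoms `"ab"`, `"c"`, `"abc"`). Symmetric metabolites are
#'   encoded as two complete mappings with weight 0.5 each.
#' * `regulations`: `reaction_id`, `inhibitor_id`, `mode` (one of
#'   `"competitive"`, `"uncompetitive"`, `"noncompetitive"`).
#' * `binding_orders`: `reaction_id`, `role`, `position`, `metabolite_id`.
#'   When omitted, substrates bind and products release in stoichiometry
#'   declaration order (coefficients expanded).
#'
#' @param metabolites,reactions,stoichiometry,atom_maps,regulations,binding_orders
#'   Data frames as described above. `atom_maps`, `regulations` and
#'   `binding_orders` may be `NULL`.
#' @param uptake_reaction Id of the substrate uptake reaction (flux basis).
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            atom_maps = NULL, regulations = NULL,
                            binding_orders = NULL, uptake_reaction = NULL) {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  stoichiometry <- as_tibble(stoichiometry)

  if (!all(c("id", "carbon_count") %in% names(metabolites))) {
    abort("`metabolites` needs columns id, carbon_count")
  }
  metabolites <- metabolites |>
    mutate(
      carbon_count = as.integer(.data$carbon_count),
      is_extracellular = if ("is_extracellular" %in% names(metabolites))
        as.logical(.data$is_extracellular) else FALSE,
      is_biomass_precursor = if ("is_biomass_precursor" %in% names(metabolites))
        as.logical(.data$is_biomass_precursor) else FALSE
    )
  if (anyDuplicated(metabolites$id)) {
    abort(paste0("duplicate metabolite id: ",
                 paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", ")))
  }
  if (any(metabolites$carbon_count < 0)) abort("carbon_count must be >= 0")

  defaults <- list(reversible = FALSE, excluded_from_fit = FALSE,
                   is_biomass_sink = FALSE, is_uptake = FALSE)
  for (nm in names(defaults)) {
    if (!nm %in% names(reactions)) reactions[[nm]] <- defaults[[nm]]
  }
  if (!"enzyme_id" %in% names(reactions)) reactions$enzyme_id <- reactions$id
  reactions$enzyme_id[is.na(reactions$enzyme_id)] <- reactions$id[is.na(reactions$enzyme_id)]
  if (anyDuplicated(reactions$id)) {
    abort(paste0("duplicate reaction id: ",
                 paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", ")))
  }

  bad <- setdiff(stoichiometry$metabolite_id, metabolites$id)
  if (length(bad)) {
    abort(paste0("stoichiometry references unknown metabolite(s): ",
                 paste(bad, collapse = ", ")))
  }
  bad <- setdiff(stoichiometry$reaction_id, reactions$id)
  if (length(bad)) {
    abort(paste0("stoichiometry references unknown reaction(s): ",
                 paste(bad, collapse = ", ")))
  }

  if (is.null(atom_maps)) {
    atom_maps <- tibble(reaction_id = character(), mapping_id = integer(),
                        weight = double(), role = character(),
                        metabolite_id = character(), atoms = character())
  } else {
    atom_maps <- as_tibble(atom_maps)
    if (!"mapping_id" %in% names(atom_maps)) atom_maps$mapping_id <- 1L
    if (!"weight" %in% names(atom_maps)) atom_maps$weight <- 1
    bad <- setdiff(atom_maps$metabolite_id, metabolites$id)
    if (length(bad)) {
      abort(paste0("atom map references unknown metabolite(s): ",
                   paste(bad, collapse = ", ")))
    }
    if (any(!grepl("^[a-z]*$", atom_maps$atoms))) {
      bad_row <- atom_maps[!grepl("^[a-z]*$", atom_maps$atoms), ]
      abort(paste0("malformed atom string '", bad_row$atoms[1], "' in reaction ",
                   bad_row$reaction_id[1]))
    }
  }

  if (is.null(regulations)) {
    regulations <- tibble(reaction_id = character(), inhibitor_id = character(),
                          mode = character())
  } else {
    regulations <- as_tibble(regulations)
    bad <- setdiff(regulations$inhibitor_id, metabolites$id)
    if (length(bad)) {
      abort(paste0("regulation references unknown metabolite(s): ",
                   paste(bad, collapse = ", ")))
    }
    bad <- setdiff(regulations$reaction_id, reactions$id)
    if (length(bad)) {
      abort(paste0("regulation references unknown reaction(s): ",
                   paste(bad, collapse = ", ")))
    }
    bad <- setdiff(regulations$mode, c("competitive", "uncompetitive", "noncompetitive"))
    if (length(bad)) {
      abort(paste0("unknown regulation mode: ", paste(bad, collapse = ", ")))
    }
  }

  if (!is.null(binding_orders)) {
    binding_orders <- as_tibble(binding_orders)
    bad <- setdiff(binding_orders$metabolite_id, metabolites$id)
    if (length(bad)) {
      abort(paste0("binding order references unknown metabolite(s): ",
                   paste(bad, collapse = ", ")))
    }
  }

  if (is.null(uptake_reaction)) {
    up <- reactions$id[reactions$is_uptake]
    uptake_reaction <- if (length(up)) up[[1]] else NA_character_
  } else {
    reactions$is_uptake <- reactions$id == uptake_reaction
  }

  structure(
    list(
      metabolites = metabolites,
      reactions = reactions,
      stoichiometry = stoichiometry,
      atom_maps = atom_maps,
      regulations = regulations,
      binding_orders = binding_orders,
      uptake_reaction = uptake_reaction
    ),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites, ",
      nrow(x$regulations), " regulations\n", sep = "")
  if (!is.na(x$uptake_reaction)) cat("uptake reaction:", x$uptake_reaction, "\n")
  invisible(x)
}

#' Stoichiometric matrix
#'
#' @param model A [metabolic_model()].
#' @param balanced_only Keep only rows for intracellular (mass-balanced)
#'   metabolites.
#' @return Numeric matrix, metabolites x reactions.
#' @export
stoichiometric_matrix <- function(model, balanced_only = FALSE) {
  mets <- model$metabolites$id
  if (balanced_only) mets <- mets[!model$metabolites$is_extracellular]
  S <- matrix(0, length(mets), nrow(model$reactions),
              dimnames = list(mets, model$reactions$id))
  st <- model$stoichiometry[model$stoichiometry$metabolite_id %in% mets, ]
  S[cbind(st$metabolite_id, st$reaction_id)] <- st$coef
  S
}

#' Validate a metabolic model
#'
#' Checks carbon conservation of every atom mapping (each atom letter on the
#' substrate side must appear exactly once on the product side), atom-string
#' lengths against metabolite carbon counts, orphan metabolites, and atom-map
#' consistency with the stoichiometry. Returns a report rather than failing, so
#' it can be used both interactively and in pipelines.
#'
#' @param model A [metabolic_model()].
#' @return A tibble with columns `check`, `reaction_id`, `detail`; zero rows
#'   for a clean model.
#' @export
validate_model <- function(model) {
  findings <- list()
  note <- function(check, reaction_id, detail) {
    findings[[length(findings) + 1]] <<- tibble(
      check = check, reaction_id = reaction_id, detail = detail)
  }

  cc <- setNames(model$metabolites$carbon_count, model$metabolites$id)

  am <- model$atom_maps
  if (nrow(am)) {
    for (key in unique(paste(am$reaction_id, am$mapping_id))) {
      rows <- am[paste(am$reaction_id, am$mapping_id) == key, ]
      rid <- rows$reaction_id[[1]]
      bad_len <- nchar(rows$atoms) != cc[rows$metabolite_id]
      if (any(bad_len)) {
        note("atom_string_length", rid,
             paste0(rows$metabolite_id[bad_len][1], ": atoms '",
                    rows$atoms[bad_len][1], "' vs carbon_count ",
                    cc[rows$metabolite_id[bad_len][1]]))
        next
      }
      sub_letters <- unlist(strsplit(rows$atoms[rows$role == "substrate"], ""))
      prod_letters <- unlist(strsplit(rows$atoms[rows$role == "product"], ""))
      if (anyDuplicated(sub_letters) || anyDuplicated(prod_letters) ||
          !setequal(sub_letters, prod_letters) ||
          length(sub_letters) != length(prod_letters)) {
        note("carbon_imbalance", rid,
             paste0("substrate atoms {", paste(sort(sub_letters), collapse = ""),
                    "} vs product atoms {", paste(sort(prod_letters), collapse = ""), "}"))
      }
    }
    # mapped species must appear in the stoichiometry with the right sign
    key_st <- paste(model$stoichiometry$reaction_id, model$stoichiometry$metabolite_id)
    miss <- !(paste(am$reaction_id, am$metabolite_id) %in% key_st)
    for (i in which(miss)) {
      note("atom_map_species_not_in_stoichiometry", am$reaction_id[i], am$metabolite_id[i])
    }
  }

  used <- unique(model$stoichiometry$metabolite_id)
  orphan <- setdiff(model$metabolites$id, used)
  for (m in orphan) note("orphan_metabolite", NA_character_, m)

  if (length(findings)) bind_rows(findings) else
    tibble(check = character(), reaction_id = character(), detail = character())
}

#' Reduce a metabolic network
#'
#' Applies reduction rules of the kind used to build simplified flux-
#' elucidation networks: dropping whole reactions (e.g. amino-acid degradation
#' pathways) and stripping non-carbon-carrying species (cofactors; nitrogen,
#' oxygen and sulfur metabolism) from the remaining reactions so that only
#' carbon transfer is retained.
#'
#' @param model A [metabolic_model()].
#' @param rules List with elements `drop_reactions` (character) and
#'   `strip_metabolites` (character); either may be empty.
#' @return A reduced `metabolic_model`; attribute `reaction_map` holds the
#'   tibble mapping reduced reaction ids to the originating full-model ids.
#' @export
reduce_network <- function(model, rules) {
  drop <- rules$drop_reactions %||% character()
  strip <- rules$strip_metabolites %||% character()
  bad <- setdiff(drop, model$reactions$id)
  if (length(bad)) {
    abort(paste0("reduction rule references absent reaction(s): ",
                 paste(bad, collapse = ", ")))
  }
  bad <- setdiff(strip, model$metabolites$id)
  if (length(bad)) {
    abort(paste0("reduction rule references absent metabolite(s): ",
                 paste(bad, collapse = ", ")))
  }

  keep_rxn <- setdiff(model$reactions$id, drop)
  reactions <- model$reactions |> filter(.data$id %in% keep_rxn)
  stoich <- model$stoichiometry |>
    filter(.data$reaction_id %in% keep_rxn, !.data$metabolite_id %in% strip)
  keep_met <- setdiff(unique(stoich$metabolite_id), strip)
  metabolites <- model$metabolites |> filter(.data$id %in% keep_met)
  atom_maps <- model$atom_maps |>
    filter(.data$reaction_id %in% keep_rxn, !.data$metabolite_id %in% strip)
  regulations <- model$regulations |>
    filter(.data$reaction_id %in% keep_rxn, !.data$inhibitor_id %in% strip)
  binding_orders <- model$binding_orders
  if (!is.null(binding_orders)) {
    binding_orders <- binding_orders |>
      filter(.data$reaction_id %in% keep_rxn, !.data$metabolite_id %in% strip)
  }

  out <- metabolic_model(metabolites, reactions, stoich, atom_maps, regulations,
                         binding_orders,
                         uptake_reaction = if (model$uptake_reaction %in% keep_rxn)
                           model$uptake_reaction else NULL)
  attr(out, "reaction_map") <- tibble(reduced_id = keep_rxn, full_id = keep_rxn)
  out
}

#' Binding and release order of a reaction
#'
#' Returns the substrate binding order and product release order for a
#' reaction, falling back to stoichiometry declaration order (coefficients
#' expanded to repeats) when no explicit order was supplied.
#'
#' @param model A [metabolic_model()].
#' @param reaction_id Reaction id.
#' @return List with character vectors `substrates` and `products`.
#' @export
reaction_orders <- function(model, reaction_id) {
  bo <- model$binding_orders
  if (!is.null(bo) && reaction_id %in% bo$reaction_id) {
    bo <- bo |> filter(.data$reaction_id == !!reaction_id) |> arrange(.data$position)
    return(list(substrates = bo$metabolite_id[bo$role == "substrate"],
                products = bo$metabolite_id[bo$role == "product"]))
  }
  st <- model$stoichiometry |> filter(.data$reaction_id == !!reaction_id)
  expand <- function(rows) {
    unlist(map2(rows$metabolite_id, abs(rows$coef), function(m, k) rep(m, round(k))))
  }
  list(substrates = expand(st[st$coef < 0, ]),
       products = expand(st[st$coef > 0, ]))
}
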