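#' Read a metabolic model from a directory of TSV sheets
#'
#' Expects `metabolites.tsv`, `reactions.tsv`, `stoichiometry.tsv` and
#' optionally `atom_maps.tsv`, `regulations.tsv`, `binding_orders.tsv`, in the
#' column layouts documented in [metabolic_model()].
#'
#' @param path Directory containing the sheets.
#' @param quiet Suppress the loaded-counts message.
#' @return A [metabolic_model()].
#' @export
read_model <- function(path, quiet = FALSE) {
  sheet <- function(name, required = TRUE) {
    f <- file.path(path, paste0(name, ".tsv"))
    if (!file.exists(f)) {
      if (required) abort(paste0("missing model sheet: ", f))
      return(NULL)
    }
    readr::read_tsv(f, show_col_types = FALSE, progress = FALSE)
  }
  model <- metabolic_model(
    metabolites = sheet("metabolites"),
    reactions = sheet("reactions"),
    stoichiometry = sheet("stoichiometry"),
    atom_maps = sheet("atom_maps", required = FALSE),
    regulations = sheet("regulations", required = FALSE),
    binding_orders = sheet("binding_orders", required = FALSE)
  )
  if (!quiet) {
    message("loaded model: ", nrow(model$reactions), " reactions, ",
            nrow(model$metabolites), " metabolites, ",
            nrow(model$regulations), " regulations")
  }
  model
}

#' Write a metabolic model as TSV sheets
#'
#' Inverse of [read_model()]; `read_model(write_model(m, d))` reproduces every
#' model field.
#'
#' @param model A [metabolic_model()].
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(model$metabolites, file.path(path, "metabolites.tsv"))
  readr::write_tsv(model$reactions, file.path(path, "reactions.tsv"))
  readr::write_tsv(model$stoichiometry, file.path(path, "stoichiometry.tsv"))
  if (nrow(model$atom_maps)) {
    readr::write_tsv(model$atom_maps, file.path(path, "atom_maps.tsv"))
  }
  if (nrow(model$regulations)) {
    readr::write_tsv(model$regulations, file.path(path, "regulations.tsv"))
  }
  if (!is.null(model$binding_orders) && nrow(model$binding_orders)) {
    readr::write_tsv(model$binding_orders, file.path(path, "binding_orders.tsv"))
  }
  invisible(path)
}

#' Write and read flux distribution tables
#'
#' Flux tables are tibbles with columns `reaction_id`, `flux` and optionally
#' `sd`, `ci_lo`, `ci_hi`, `strain_id`; units are mmol per 100 mmol wild-type
#' glucose (substrate) uptake.
#'
#' @param fluxes Flux tibble.
#' @param path TSV file path.
#' @return `read_flux_tsv()` returns the tibble; `write_flux_tsv()` returns
#'   `path` invisibly.
#' @export
write_flux_tsv <- function(fluxes, path) {
  readr::write_tsv(as_tibble(fluxes), path)
  invisible(path)
}

#' @rdname write_flux_tsv
#' @export
read_flux_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write and read structured results as JSON
#'
#' Lossless (full double precision) round-trip for list-like result objects
#' such as kinetic fit results and sensitivity reports.
#'
#' @param x Result object (list; tibble components allowed).
#' @param path JSON file path.
#' @return `read_json_result()` returns the list; classes recorded at write
#'   time are restored.
#' @export
write_json_result <- function(x, path) {
  cls <- class(x)
  jsonlite::write_json(list(class = cls, value = unclass(x)), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_json_result
#' @export
read_json_result <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- obj$value
  if (!identical(obj$class, "list")) class(out) <- unlist(obj$class)
  out
}
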