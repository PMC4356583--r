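# Versioned JSON serialization of fitted ensembles: architecture, weights,
# per-member preprocessing statistics and the time grid, written at full
# numeric precision so a reloaded model reproduces predictions to within
# floating-point round-off.

MODEL_FORMAT_VERSION <- 1L

design_to_list <- function(d) {
  list(
    variables = d$variables,
    reference_levels = d$reference_levels,
    column_names = d$column_names,
    column_kinds = as.list(d$column_kinds),
    centers = d$centers,
    scales = d$scales,
    increments = as.list(d$increments),
    levels = d$levels,
    add_ratios = d$add_ratios
  )
}

design_from_list <- function(l) {
  schema <- ihtsa_schema()
  kinds <- unlist(l$column_kinds)
  structure(
    list(
      column_names = unlist(l$column_names),
      column_kinds = setNames(as.character(kinds), names(kinds)),
      centers = as.numeric(unlist(l$centers)),
      scales = as.numeric(unlist(l$scales)),
      increments = vapply(l$increments, as.numeric, numeric(1)),
      variables = unlist(l$variables),
      reference_levels = l$reference_levels,
      levels = l$levels,
      add_ratios = isTRUE(l$add_ratios),
      schema = schema[schema$name %in% unlist(l$variables), , drop = FALSE]
    ),
    class = "ihtsa_design"
  )
}

network_to_list <- function(net) {
  list(
    W1 = net$W1, b1 = net$b1, W2 = net$W2, b2 = net$b2,
    input_dim = net$input_dim, hidden = net$hidden, K = net$K,
    training_meta = net$training_meta
  )
}

network_from_list <- function(l, grid) {
  structure(
    list(
      W1 = do.call(rbind, lapply(l$W1, unlist)),
      b1 = as.numeric(unlist(l$b1)),
      W2 = do.call(rbind, lapply(l$W2, unlist)),
      b2 = as.numeric(unlist(l$b2)),
      input_dim = as.integer(l$input_dim),
      hidden = as.integer(l$hidden),
      K = as.integer(l$K),
      grid = grid,
      training_meta = l$training_meta
    ),
    class = "ihtsa_network"
  )
}

#' Save a fitted ensemble to versioned JSON
#'
#' @param model An `ihtsa_ensemble`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ihtsa_ensemble"))
  payload <- list(
    format = "ihtsa_ensemble",
    version = MODEL_FORMAT_VERSION,
    aggregation = model$aggregation,
    seed = model$seed,
    grid_boundaries = model$grid$boundaries,
    variables = model$variables,
    members = lapply(model$members, network_to_list),
    designs = lapply(model$designs, design_to_list)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a fitted ensemble from JSON
#'
#' @param path Path written by [write_model()].
#' @return An `ihtsa_ensemble`.
#' @export
read_model <- function(path) {
  l <- jsonlite::read_json(path)
  if (!identical(l$format, "ihtsa_ensemble")) {
    abort("not an ihtsa model file", class = "ihtsa_io_error")
  }
  boundaries <- as.numeric(unlist(l$grid_boundaries))
  grid <- structure(
    list(boundaries = boundaries, K = length(boundaries) - 1),
    class = "ihtsa_time_grid"
  )
  structure(
    list(
      members = lapply(l$members, network_from_list, grid = grid),
      designs = lapply(l$designs, design_from_list),
      grid = grid,
      variables = unlist(l$variables),
      aggregation = l$aggregation,
      seed = l$seed
    ),
    class = "ihtsa_ensemble"
  )
}
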