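# Structured-text configuration and CSV I/O.

#' Write / read a model configuration
#'
#' The configuration is the full named parameter registry
#' ([lung_model_params()]) serialized as YAML; reading rebuilds the identical
#' model through [build_lung_model()], so write -> read round-trips.
#'
#' @param model A `lung_model`.
#' @param path File path (YAML).
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns a `lung_model`.
#' @export
write_model_config <- function(model, path) {
  yaml::write_yaml(list(model = "lung_mitochondria_bioenergetics",
                        parameters = model$params), path,
                   precision = 15)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$parameters)) stop("config has no 'parameters' block: ", path)
  build_lung_model(cfg$parameters)
}

#' Write / read a protocol description
#'
#' @param events Event tibble ([respirometry_events()]) or `NULL`.
#' @param conditions A [protocol_conditions()].
#' @param t_end Simulation end, min.
#' @param path File path (YAML).
#' @return `write_protocol()` returns `path` invisibly; `read_protocol()`
#'   returns `list(events, conditions, t_end)`.
#' @export
write_protocol <- function(events, conditions, t_end, path) {
  yaml::write_yaml(list(
    conditions = unclass(conditions), t_end = t_end,
    events = if (!is.null(events)) lapply(seq_len(nrow(events)), function(i)
      as.list(events[i, ]))), path, precision = 15)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  cfg <- yaml::read_yaml(path)
  conditions <- do.call(protocol_conditions, cfg$conditions)
  events <- if (!is.null(cfg$events))
    dplyr::bind_rows(lapply(cfg$events, tibble::as_tibble))
  list(events = events, conditions = conditions,
       t_end = cfg$t_end %||% 10)
}

#' Export simulation traces as CSV
#'
#' Columns: `time_min`, one column per state (species as
#' `<SPECIES>.<compartment>` in mM, proton pools in M, `deltaPsi_mV`), and
#' `flux_<NAME>` per flux (nmol min-1 mg-1).
#'
#' @param result A `mito_sim`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(result, path) {
  tr <- result$trajectory
  names(tr)[1] <- "time_min"
  names(tr)[names(tr) == "dPsi"] <- "deltaPsi_mV"
  fl <- result$fluxes[-1]
  names(fl) <- paste0("flux_", names(fl))
  utils::write.csv(dplyr::bind_cols(tr, fl), path, row.names = FALSE)
  invisible(path)
}

#' Read a two-column time-series CSV
#'
#' Accepts fluorimetry or oximetry exports: first column time (min), second
#' the signal/concentration. Additional columns are kept.
#'
#' @param path CSV path with a header row.
#' @return Tibble with at least `time` and `value`.
#' @export
read_timeseries_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("expected at least two columns in ", path)
  names(df)[1:2] <- c("time", "value")
  tibble::as_tibble(df)
}

#' One-line JSON summary of a respirometry simulation
#'
#' @param result A `mito_sim` with an ADP event.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
write_summary_json <- function(result, path = NULL) {
  s <- respiration_summary(result)
  js <- jsonlite::toJSON(as.list(s), auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
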