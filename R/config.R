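# Package configuration and structured logging.

#' Default configuration
#'
#' Flat configuration with dotted keys, covering the thresholds and
#' namespaces used across the package:
#' \describe{
#'   \item{derivative.threshold}{minimum alignment identity for a derivative
#'     (`similarTo`) edge; default 0.95.}
#'   \item{candidate.threshold}{minimum name/sequence match score for editor
#'     key candidates; default 0.8.}
#'   \item{kmer.k}{k-mer size of the all-pairs prescreen; default 8.}
#'   \item{kmer.min_jaccard}{minimum k-mer Jaccard to run an alignment;
#'     default 0.3. A pair at the 0.95 identity floor can lose up to
#'     8 k-mers per substitution, driving its Jaccard down to roughly 0.4
#'     in the worst case, so the floor sits safely below that bound and
#'     the prescreen never changes which derivative pairs are found.}
#'   \item{mint.namespace}{namespace under which edit-minted interaction
#'     keys are created.}
#'   \item{rules.path}{optional path to a JSON predicate rule table.}
#' }
#'
#' @return Named list of configuration values.
#' @export
cg_config <- function() {
  list(
    "derivative.threshold" = 0.95,
    "candidate.threshold" = 0.8,
    "kmer.k" = 8L,
    "kmer.min_jaccard" = 0.3,
    "mint.namespace" = "https://circuitgraph.local/edit",
    "rules.path" = "",
    "presets" = list(
      "interaction standard" = list(view = "interaction", mode = "network"),
      "hierarchy" = list(view = "hierarchy", mode = "network"),
      "protein network" = list(view = "protein_network", mode = "network")
    )
  )
}

#' Load configuration from a flat YAML document with dotted keys
#'
#' Values present in the file override the defaults of [cg_config()];
#' unknown keys are kept (the config round-trips losslessly through
#' [write_config()]).
#'
#' @param path Path to a YAML file.
#' @return Named list of configuration values.
#' @export
load_config <- function(path) {
  cfg <- cg_config()
  user <- yaml::read_yaml(path)
  for (k in names(user)) cfg[[k]] <- user[[k]]
  for (k in c("derivative.threshold", "candidate.threshold",
              "kmer.min_jaccard")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      stop(sprintf("config %s must lie in (0,1)", k))
    }
  }
  cfg
}

#' Write configuration to a YAML file
#'
#' @param cfg Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

.log_levels <- c(debug = 0L, info = 1L, warn = 2L, error = 3L)

#' Set the logging threshold
#'
#' @param level One of `debug`, `info`, `warn`, `error`.
#' @return Previous level, invisibly.
#' @export
cg_log_level <- function(level = c("warn", "debug", "info", "error")) {
  level <- match.arg(level)
  old <- getOption("circuitgraph.log_level", "warn")
  options(circuitgraph.log_level = level)
  invisible(old)
}

#' Emit a structured log line
#'
#' Writes `LEVEL [module] message` to the message stream when `level` is at
#' or above the current threshold (see [cg_log_level()]).
#'
#' @param level One of `debug`, `info`, `warn`, `error`.
#' @param module Originating module name.
#' @param msg Message text.
#' @return Invisibly, whether the line was emitted.
#' @keywords internal
cg_log <- function(level, module, msg) {
  thr <- getOption("circuitgraph.log_level", "warn")
  emit <- .log_levels[[level]] >= .log_levels[[thr]]
  if (emit) message(sprintf("%s [%s] %s", toupper(level), module, msg))
  invisible(emit)
}
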