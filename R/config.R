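#' Load a run configuration
#'
#' A single structured plain-text (YAML) file carries every overridable
#' default: `architecture` (lengths for [architecture_spec()]), `signal`
#' (the [signal_model()] parameters), `engine` ([engine_params()]),
#' `sequence` ([generate_sequences()] constraints) and a `seed`. Missing
#' sections fall back to the built-in defaults. Dotted-key overrides
#' (e.g. `signal.threshold=0.5`) take final precedence.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @param overrides Character vector of `section.key=value` overrides.
#' @return A list with validated components: `spec`, `lib`, `model`,
#'   `engine`, `sequence`, `seed`, plus the raw `config` list.
#' @export
load_run_config <- function(path = NULL, overrides = character(0)) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad override: ", ov, call. = FALSE)
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    val <- utils::type.convert(kv[2], as.is = TRUE)
    if (length(keys) == 1) {
      cfg[[keys]] <- val
    } else {
      cfg[[keys[1]]][[keys[2]]] <- val
    }
  }
  spec <- do.call(architecture_spec, cfg$architecture %||% list())
  model <- do.call(signal_model, cfg$signal %||% list())
  engine <- do.call(engine_params, cfg$engine %||% list())
  seed <- cfg$seed %||% 1L
  list(spec = spec, lib = build_canonical_strands(spec), model = model,
       engine = engine, sequence = cfg$sequence %||% list(),
       seed = as.integer(seed), config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
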