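#' Define a logic gate on the prism platform
#'
#' A gate maps each value of each input to a multiset of strand species
#' (value 0 is always the empty multiset: absence of the input strand),
#' and decodes the final structure either by thresholding the NFI
#' (binary) or by classifying the final structure (ternary).
#'
#' @param name Gate name.
#' @param inputs A list with one element per input; each element is a list
#'   of character vectors indexed by value + 1 (so `inputs[[i]][[1]]` must
#'   be `character(0)`).
#' @param valence 2 for binary, 3 for ternary inputs/outputs.
#' @param decoder `"threshold"` (output `[NFI > threshold]`) or
#'   `"structure"` (ternary classifier: closed -> 0, mono-SD(C1) -> 1,
#'   di-SD(C1/C2) -> 2).
#' @param lib Strand library the encoding must come from.
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(name, inputs, valence = 2,
                      decoder = c("threshold", "structure"),
                      lib = build_canonical_strands(architecture_spec())) {
  decoder <- match.arg(decoder)
  stopifnot(valence %in% c(2, 3))
  for (inp in inputs) {
    if (length(inp) != valence) {
      stop("each input must map all ", valence, " values", call. = FALSE)
    }
    if (length(inp[[1]]) != 0) {
      stop("value 0 must encode the empty strand multiset", call. = FALSE)
    }
    unknown <- setdiff(unlist(inp), names(lib$strands))
    if (length(unknown) > 0) {
      stop("encoding references unknown strands: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(name = name, arity = length(inputs), valence = valence,
                 inputs = inputs, decoder = decoder),
            class = "gate_spec")
}

#' @export
print.gate_spec <- function(x, ...) {
  cat(sprintf("<gate_spec> %s: %d input(s), %s-valued, %s decoder\n",
              x$name, x$arity, if (x$valence == 2) "binary" else "ternary",
              x$decoder))
  invisible(x)
}

binary_input <- function(species) list(character(0), species)

#' The built-in gate library
#'
#' The seven gates realized on the single prism work unit:
#' \describe{
#'   \item{OR}{inputs C1 and C2; either opener reconfigures the prism.}
#'   \item{AND}{caged hairpin input 1 plus activator input 2 (C3 + 2-nt
#'     toehold); only together do they unfasten edge 2.}
#'   \item{XOR}{doubly extended C1/C2; together the extensions pair the
#'     two inputs with each other instead of the prism.}
#'   \item{INHIBIT}{C1 against its full complement C1p, which sequesters
#'     it in solution.}
#'   \item{INHIBIT-OR}{three-input combination C1, C1p, C2.}
#'   \item{INHIBIT-OR-2}{three-input combination C1, C2, C2p.}
#'   \item{ternary-INHIBIT}{input 1 values 0/1/2 = {}, C1, C1+C2; input 2
#'     values 0/1/2 = {}, C2p, C2p+C1p; output decoded from the final
#'     structure.}
#' }
#'
#' @param lib A strand library.
#' @return Named list of [gate_spec()] objects.
#' @export
builtin_gates <- function(lib = build_canonical_strands(architecture_spec())) {
  gates <- list(
    gate_spec("OR", list(binary_input("C1"), binary_input("C2")), lib = lib),
    gate_spec("AND", list(binary_input("C2H"), binary_input("AND2")),
              lib = lib),
    gate_spec("XOR", list(binary_input("XOR1"), binary_input("XOR2")),
              lib = lib),
    gate_spec("INHIBIT", list(binary_input("C1"), binary_input("C1p")),
              lib = lib),
    gate_spec("INHIBIT-OR",
              list(binary_input("C1"), binary_input("C1p"),
                   binary_input("C2")), lib = lib),
    gate_spec("INHIBIT-OR-2",
              list(binary_input("C1"), binary_input("C2"),
                   binary_input("C2p")), lib = lib),
    gate_spec("ternary-INHIBIT",
              list(list(character(0), "C1", c("C1", "C2")),
                   list(character(0), "C2p", c("C2p", "C1p"))),
              valence = 3, decoder = "structure", lib = lib)
  )
  stats::setNames(gates, vapply(gates, `[[`, character(1), "name"))
}

ternary_decode <- function(label) {
  out <- c("closed" = 0L, "mono-SD(C1)" = 1L, "di-SD(C1/C2)" = 2L)[label]
  if (is.na(out)) {
    stop("decode error: final structure '", label,
         "' is not mapped by the ternary decoder", call. = FALSE)
  }
  unname(out)
}

#' Evaluate a gate at one input vector
#'
#' Encodes the input values to their strand multiset, mixes all inputs
#' with a freshly assembled closed prism in a single event, runs the
#' reaction engine to its fixed point, computes the NFI of the final
#' structure and decodes the output.
#'
#' @param gate A [gate_spec()].
#' @param inputs Integer vector of input values (length = gate arity,
#'   each in `0:(valence-1)`).
#' @param lib Strand library.
#' @param model Signal model.
#' @param params Engine parameters.
#' @return An object of class `gate_evaluation`: inputs, final state,
#'   NFI, decoded output and the reaction system (with trace).
#' @examples
#' gates <- builtin_gates()
#' ev <- evaluate_gate(gates$OR, c(0, 1))
#' ev$output  # 1, via mono-SD(C2)
#' @export
evaluate_gate <- function(gate, inputs,
                          lib = build_canonical_strands(architecture_spec()),
                          model = signal_model(), params = engine_params()) {
  stopifnot(inherits(gate, "gate_spec"))
  if (length(inputs) != gate$arity) {
    stop("input error: expected ", gate$arity, " input value(s)",
         call. = FALSE)
  }
  if (any(inputs < 0 | inputs >= gate$valence | inputs != round(inputs))) {
    stop("input error: values must lie in 0:", gate$valence - 1,
         call. = FALSE)
  }
  species <- unlist(lapply(seq_along(inputs), function(i)
    gate$inputs[[i]][[inputs[i] + 1]]))
  prism <- assemble_prism(lib)
  sys <- reaction_system(lib, list(prism), free = species, params = params)
  sys <- react_to_fixed_point(sys)
  st <- prism_state(sys)
  value <- nfi(st, model)
  output <- if (gate$decoder == "threshold") {
    as.integer(value > model$threshold)
  } else {
    ternary_decode(st$label)
  }
  structure(list(gate = gate$name, inputs = as.integer(inputs),
                 state = st, nfi = value, output = output,
                 threshold = model$threshold, system = sys),
            class = "gate_evaluation")
}

#' @export
print.gate_evaluation <- function(x, ...) {
  cat(sprintf("<gate_evaluation> %s(%s) -> [%d]  (%s, NFI %.3f)\n",
              x$gate, paste(x$inputs, collapse = "/"), x$output,
              x$state$label, x$nfi))
  invisible(x)
}

#' @rdname evaluate_gate
#' @param x A `gate_evaluation`.
#' @param ... Unused.
#' @return `tidy()`: one-row tibble with the inputs, final structure,
#'   NFI and output.
#' @export
tidy.gate_evaluation <- function(x, ...) {
  row <- tibble::as_tibble(stats::setNames(
    as.list(x$inputs), paste0("in", seq_along(x$inputs))))
  dplyr::bind_cols(tibble::tibble(gate = x$gate), row,
                   tibble::tibble(state = x$state$label,
                                  nfi = x$nfi, output = x$output))
}

#' Full truth table of a gate
#'
#' Evaluates all `valence^arity` input vectors in lexicographic order
#' (first input most significant).
#'
#' @param gate A [gate_spec()].
#' @inheritParams evaluate_gate
#' @return A tibble of class `prism_truth_table`: one row per input
#'   vector with the final structure, NFI and decoded output.
#' @examples
#' truth_table(builtin_gates()$OR)$output  # 0 1 1 1
#' @export
truth_table <- function(gate,
                        lib = build_canonical_strands(architecture_spec()),
                        model = signal_model(), params = engine_params()) {
  stopifnot(inherits(gate, "gate_spec"))
  grid <- expand.grid(rep(list(seq_len(gate$valence) - 1L), gate$arity))
  grid <- grid[, rev(seq_len(gate$arity)), drop = FALSE]
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  names(grid) <- paste0("in", seq_len(gate$arity))
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    tidy(evaluate_gate(gate, unlist(grid[k, ]), lib = lib,
                       model = model, params = params))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("prism_truth_table", class(out))
  attr(out, "gate") <- gate$name
  attr(out, "valence") <- gate$valence
  attr(out, "threshold") <- model$threshold
  out
}

#' @export
glance.prism_truth_table <- function(x, ...) {
  tibble::tibble(
    gate = attr(x, "gate"),
    arity = sum(startsWith(names(x), "in")),
    valence = attr(x, "valence"),
    n_rows = nrow(x),
    n_true = sum(x$output > 0)
  )
}

#' Binary-coded-decimal encoding of a digit
#'
#' Standard 8421 BCD: the digit as a four-bit binary number
#' `(N4, N3, N2, N1)`.
#'
#' @param digit Integer in `0:9`.
#' @return Named integer vector `c(N4, N3, N2, N1)`.
#' @examples
#' encode_bcd(7)  # 0 1 1 1
#' @export
encode_bcd <- function(digit) {
  if (length(digit) != 1 || is.na(digit) || digit < 0 || digit > 9 ||
      digit != round(digit)) {
    stop("input error: digit must be a single integer in 0:9", call. = FALSE)
  }
  bits <- as.integer(intToBits(as.integer(digit))[4:1])
  stats::setNames(bits, c("N4", "N3", "N2", "N1"))
}

bcd_species <- c(N4 = "C2H", N3 = "AND2", N2 = "C1p", N1 = "C2")

#' Identify the parity of a decimal digit with the prism
#'
#' BCD-encodes the digit and maps the four bits to the four input strands
#' of the even/odd identification system (`N4` -> hairpin C2H, `N3` ->
#' the C3-type activator, `N2` -> C1p, `N1` -> C2), runs the engine and
#' thresholds the NFI: the output is 1 exactly for odd digits.
#'
#' @param digit Integer in `0:9`.
#' @inheritParams evaluate_gate
#' @return A `gate_evaluation` (gate name `even-odd`).
#' @export
classify_parity <- function(digit,
                            lib = build_canonical_strands(architecture_spec()),
                            model = signal_model(),
                            params = engine_params()) {
  bits <- encode_bcd(digit)
  species <- unname(bcd_species[names(bits)[bits == 1]])
  prism <- assemble_prism(lib)
  sys <- reaction_system(lib, list(prism), free = species, params = params)
  sys <- react_to_fixed_point(sys)
  st <- prism_state(sys)
  value <- nfi(st, model)
  structure(list(gate = "even-odd", inputs = unname(bits), state = st,
                 nfi = value, output = as.integer(value > model$threshold),
                 threshold = model$threshold, system = sys),
            class = "gate_evaluation")
}

#' Even/odd identification table for the digits 0-9
#'
#' @inheritParams classify_parity
#' @param digits Digits to classify.
#' @return A tibble of class `prism_parity_table`: digit, BCD bits, final
#'   structure, NFI and output (= digit parity).
#' @export
parity_table <- function(digits = 0:9,
                         lib = build_canonical_strands(architecture_spec()),
                         model = signal_model(), params = engine_params()) {
  rows <- lapply(digits, function(d) {
    ev <- classify_parity(d, lib = lib, model = model, params = params)
    bits <- encode_bcd(d)
    tibble::tibble(digit = d, N4 = bits[["N4"]], N3 = bits[["N3"]],
                   N2 = bits[["N2"]], N1 = bits[["N1"]],
                   state = ev$state$label, nfi = ev$nfi, output = ev$output)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("prism_parity_table", class(out))
  attr(out, "threshold") <- model$threshold
  out
}

#' Cycle an edge between the opened and closed states
#'
#' Alternately adds the erasable opener (Is) and its eraser (Es) on one
#' vertical edge, running the engine to a fixed point after each
#' addition. The NFI alternates above/below the decision threshold and
#' the prism finishes closed.
#'
#' @param edge 1 or 2.
#' @param n_cycles Number of open/erase rounds (>= 1).
#' @inheritParams evaluate_gate
#' @return A tibble of class `prism_cycle`: one row per half-cycle with
#'   the action, final structure and NFI (`2 * n_cycles` rows).
#' @examples
#' run_cycle(1, 3)$nfi  # alternates high / low three times
#' @export
run_cycle <- function(edge, n_cycles,
                      lib = build_canonical_strands(architecture_spec()),
                      model = signal_model(), params = engine_params()) {
  if (!edge %in% c(1, 2)) {
    stop("input error: edge must be 1 or 2 (the dye-adjacent edges)",
         call. = FALSE)
  }
  if (length(n_cycles) != 1 || n_cycles < 1 || n_cycles != round(n_cycles)) {
    stop("input error: n_cycles must be a positive integer", call. = FALSE)
  }
  is_name <- paste0("Is", edge)
  es_name <- paste0("Es", edge)
  sys <- reaction_system(lib, list(assemble_prism(lib)), params = params)
  rows <- list()
  for (cycle in seq_len(n_cycles)) {
    sys <- react_to_fixed_point(add_inputs(sys, is_name))
    st <- prism_state(sys)
    rows[[length(rows) + 1]] <- tibble::tibble(
      cycle = cycle, action = "open", strand = is_name,
      state = st$label, nfi = nfi(st, model))
    sys <- erase(sys, es_name)
    st <- prism_state(sys)
    rows[[length(rows) + 1]] <- tibble::tibble(
      cycle = cycle, action = "erase", strand = es_name,
      state = st$label, nfi = nfi(st, model))
  }
  out <- dplyr::bind_rows(rows)
  out$step <- seq_len(nrow(out))
  out <- out[, c("step", "cycle", "action", "strand", "state", "nfi")]
  class(out) <- c("prism_cycle", class(out))
  attr(out, "threshold") <- model$threshold
  attr(out, "system") <- sys
  out
}

#' Write a truth table to CSV and/or JSON
#'
#' @param tt A `prism_truth_table` (or any tibble).
#' @param csv,json Output paths (`NULL` to skip either).
#' @return Invisibly, the written paths.
#' @export
write_truth_table <- function(tt, csv = NULL, json = NULL) {
  if (!is.null(csv)) {
    utils::write.csv(as.data.frame(tt), csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(as.data.frame(tt), json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(c(csv = csv, json = json))
}
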