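# Shared fixtures, memoized so the library and gate set are built once.
.memo <- new.env(parent = emptyenv())

test_lib <- function() {
  if (is.null(.memo$lib)) {
    .memo$lib <- build_canonical_strands(architecture_spec())
  }
  .memo$lib
}

test_gates <- function() {
  if (is.null(.memo$gates)) .memo$gates <- builtin_gates(test_lib())
  .memo$gates
}

test_seqs <- function(seed = 1) {
  key <- paste0("seqs", seed)
  if (is.null(.memo[[key]])) {
    .memo[[key]] <- generate_sequences(test_lib(), seed = seed)
  }
  .memo[[key]]
}

# Fresh reaction system: closed prism plus free inputs.
mk_sys <- function(free = character(0), lib = test_lib(), ...) {
  reaction_system(lib, list(assemble_prism(lib)), free = free,
                  params = engine_params(...))
}

# Independent O(n^2 m^2) oracle for the complementary-stretch scan: try
# every substring of s1 against the full reverse complement of s2.
brute_stretch <- function(s1, s2) {
  rc2 <- paste(rev(strsplit(chartr("ACGT", "TGCA", s2), "")[[1]]),
               collapse = "")
  n <- nchar(s1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 <= best) next
      if (grepl(substr(s1, i, j), rc2, fixed = TRUE)) best <- j - i + 1
    }
  }
  best
}

# Strand multiset a gate encodes for a given input vector.
gate_species <- function(gate, vals) {
  unlist(lapply(seq_along(vals), function(i) gate$inputs[[i]][[vals[i] + 1]]))
}

# Unpaired (single-stranded) nucleotides per strand instance of a complex.
unpaired_nt <- function(lib, cx) {
  out <- integer(0)
  for (inst in names(cx$strands)) {
    s <- cx$strands[[inst]]
    paired <- rep(FALSE, length(s$domains))
    b <- cx$bonds
    for (k in seq_len(nrow(b))) {
      if (b$s1[k] == inst) paired[b$p1[k]] <- TRUE
      if (b$s2[k] == inst) paired[b$p2[k]] <- TRUE
    }
    lens <- vapply(s$domains, function(d)
      prismlogic:::dom_len(lib, d), integer(1))
    out[[inst]] <- sum(lens[!paired])
  }
  out
}
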