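#' Architecture of the triangular-prism platform
#'
#' An architecture specification fixes every length (in nucleotides) that the
#' prism design depends on: the 21-bp face sides, the 10-nt A-face tails, the
#' 16-nt B-face tails whose terminal 6 nt protrude as toeholds on the three
#' vertical edges, the 10-nt external toehold of erase strands, the 10/14-nt
#' XOR input extensions and the 2-nt extra toehold of the AND-gate input.
#'
#' The defaults encode the published design; every value can be overridden,
#' subject to the structural invariants below.
#'
#' @param face_bp Length of each face side in base pairs (two helical turns).
#' @param a_tail Length of the single-stranded tails of the A-face motif (nt).
#'   These tails form the 10-bp vertical edges of the closed prism.
#' @param b_tail Length of the single-stranded tails of the B-face motif (nt).
#'   Must equal `a_tail + toehold`: the part not paired with an A tail is the
#'   exposed edge toehold.
#' @param toehold Length of the exposed edge toeholds (nt).
#' @param erase_toehold Length of the external 5' toehold carried by opener
#'   strands that are meant to be erasable (nt).
#' @param xor_ext5,xor_ext3 Lengths of the 5' and 3' extensions added to C1
#'   and C2 to build the XOR inputs (nt). `xor_ext3` must exceed `xor_ext5`.
#' @param and_extra Length of the extra 3' toehold on the AND-gate input 2
#'   (nt); also the smallest toehold the reaction engine will act on.
#' @param hairpin_loop Loop length of the AND-gate hairpin input (nt).
#'
#' @return An object of class `prism_architecture`: a validated list of the
#'   above lengths.
#' @examples
#' spec <- architecture_spec()
#' spec$b_tail == spec$a_tail + spec$toehold
#' @export
architecture_spec <- function(face_bp = 21, a_tail = 10, b_tail = 16,
                              toehold = 6, erase_toehold = 10,
                              xor_ext5 = 10, xor_ext3 = 14,
                              and_extra = 2, hairpin_loop = 4) {
  spec <- list(
    face_bp = face_bp, a_tail = a_tail, b_tail = b_tail, toehold = toehold,
    erase_toehold = erase_toehold, xor_ext5 = xor_ext5, xor_ext3 = xor_ext3,
    and_extra = and_extra, hairpin_loop = hairpin_loop
  )
  bad <- names(spec)[!vapply(spec, function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0 && x == round(x),
    logical(1))]
  if (length(bad) > 0) {
    stop("architecture lengths must be positive integers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  spec <- lapply(spec, as.integer)
  if (spec$b_tail != spec$a_tail + spec$toehold) {
    stop("invalid architecture: b_tail must equal a_tail + toehold (",
         spec$a_tail, " + ", spec$toehold, " != ", spec$b_tail, ")",
         call. = FALSE)
  }
  if (spec$a_tail <= spec$toehold) {
    stop("invalid architecture: a_tail must exceed toehold so the hairpin ",
         "stem can cage the toehold-complement block", call. = FALSE)
  }
  if (spec$xor_ext3 <= spec$xor_ext5) {
    stop("invalid architecture: xor_ext3 must exceed xor_ext5", call. = FALSE)
  }
  structure(spec, class = "prism_architecture")
}

#' @export
print.prism_architecture <- function(x, ...) {
  cat("<prism_architecture>\n")
  for (nm in names(x)) cat(sprintf("  %-14s %d nt\n", nm, x[[nm]]))
  invisible(x)
}

# Complement naming: a domain `d` has Watson-Crick partner `d*`.
dom_is_comp <- function(name) endsWith(name, "*")

dom_base <- function(name) sub("\\*$", "", name)

#' Watson-Crick partner of a domain
#'
#' Complementation is an involution over the domain registry of a strand
#' library: `domain_complement(domain_complement(d)) == d`, and lengths are
#' preserved.
#'
#' @param lib A strand library from [build_canonical_strands()].
#' @param name A domain name; `"d*"` denotes the complement of `"d"`.
#' @return The name of the unique partner domain.
#' @examples
#' lib <- build_canonical_strands(architecture_spec())
#' domain_complement(lib, "t1")
#' domain_complement(lib, "t1*")
#' @export
domain_complement <- function(lib, name) {
  stopifnot(inherits(lib, "strand_library"))
  if (!dom_base(name) %in% names(lib$domains)) {
    stop("unknown domain: ", name, call. = FALSE)
  }
  dom_partner(name)
}

# Partner name without registry lookup (internal hot path).
dom_partner <- function(name) {
  ifelse(dom_is_comp(name), dom_base(name), paste0(name, "*"))
}

# Length of a (possibly complemented) domain.
dom_len <- function(lib, name) {
  unname(lib$domains[dom_base(name)])
}

new_strand <- function(name, domains, hairpin = NULL) {
  structure(list(name = name, domains = domains, hairpin = hairpin),
            class = "prism_strand")
}

#' @export
print.prism_strand <- function(x, ...) {
  cat(sprintf("<prism_strand> %s: 5'-[%s]-3'%s\n", x$name,
              paste(x$domains, collapse = " "),
              if (is.null(x$hairpin)) "" else " (hairpin)"))
  invisible(x)
}

#' Build the canonical strand set of the prism platform
#'
#' Constructs the domain registry and every strand of the platform: the two
#' central strands (`LA`, `LB`), the face short strands `A1`-`A3` (10-nt
#' tails) and `B1`-`B3` (16-nt tails ending in a 6-nt toehold), the opener
#' strands `C1`-`C3` (each the full complement of one B tail), the inhibitor
#' complements `C1p`/`C2p`, the caged AND-gate hairpin `C2H` and its
#' activator `AND2` (C3 plus a 2-nt toehold), the doubly extended XOR inputs
#' `XOR1`/`XOR2`, and the erasable opener/eraser pairs `Is1`/`Es1`,
#' `Is2`/`Es2`.
#'
#' The hairpin input embeds the C2 block; its stem arm is the complement of
#' the 10-nt 5' head of C2, so the activator (which ends up hybridized to
#' that arm) necessarily shares that 10-mer with C2. This is realized by
#' letting edge 3's displacement block reuse edge 2's toehold-complement
#' domains, mirroring the slight sequence modification of C2/C3 required by
#' the AND design.
#'
#' The output is seed-independent: only nucleotide assignment (see
#' [generate_sequences()]) involves randomness.
#'
#' @param spec A [architecture_spec()].
#' @return An object of class `strand_library`: list with the `spec`, the
#'   base-`domains` registry (named integer lengths) and the named `strands`.
#' @examples
#' lib <- build_canonical_strands(architecture_spec())
#' strand_length(lib, "C1")    # 16 nt, the full B1-tail complement
#' strand_length(lib, "XOR1")  # 10 + 16 + 14 = 40 nt
#' @export
build_canonical_strands <- function(spec = architecture_spec()) {
  stopifnot(inherits(spec, "prism_architecture"))
  a2x <- spec$a_tail - spec$toehold    # cage block beyond the toehold head
  a2y <- spec$a_tail - a2x             # remainder of the edge-2 A tail
  z <- spec$xor_ext3 - spec$xor_ext5   # short 3' block of the XOR register

  domains <- c(
    f1a = spec$face_bp, f2a = spec$face_bp, f3a = spec$face_bp,
    f1b = spec$face_bp, f2b = spec$face_bp, f3b = spec$face_bp,
    a1d = spec$a_tail, a2x = a2x, a2y = a2y,
    t1 = spec$toehold, t2 = spec$toehold, t3 = spec$toehold,
    g = spec$and_extra, loop = spec$hairpin_loop,
    e1 = spec$erase_toehold, e2 = spec$erase_toehold,
    x1 = spec$xor_ext5, y2 = spec$xor_ext5, z = z
  )
  domains <- vapply(domains, as.integer, integer(1))

  strands <- list(
    # Face motifs: one central strand plus three shorts per face; each face
    # side is a single rigid 21-bp duplex domain (not displaceable).
    new_strand("LA", c("f1a", "f2a", "f3a")),
    new_strand("A1", c("f1a*", "a1d")),
    new_strand("A2", c("f2a*", "a2x", "a2y")),
    new_strand("A3", c("f3a*", "t2*", "a2x")),
    new_strand("LB", c("f1b", "f2b", "f3b")),
    new_strand("B1", c("f1b*", "a1d*", "t1")),
    new_strand("B2", c("f2b*", "a2y*", "a2x*", "t2")),
    new_strand("B3", c("f3b*", "a2x*", "t2", "t3")),
    # Openers: full complements of the 16-nt B tails (toehold + stem).
    new_strand("C1", c("t1*", "a1d")),
    new_strand("C2", c("t2*", "a2x", "a2y")),
    new_strand("C3", c("t3*", "t2*", "a2x")),
    # Inhibitor strands: full complements of C1 / C2.
    new_strand("C1p", c("a1d*", "t1")),
    new_strand("C2p", c("a2y*", "a2x*", "t2")),
    # AND gate: caged hairpin input 1 (embeds C2; stem cages the
    # toehold-complement head) and activator input 2 (C3 + 2-nt toehold).
    new_strand("C2H", c("g*", "a2x*", "t2", "loop", "t2*", "a2x", "a2y"),
               hairpin = list(c(2L, 6L), c(3L, 5L))),
    new_strand("AND2", c("t3*", "t2*", "a2x", "g")),
    # XOR inputs: C1/C2 extended by 10 nt (5') and 14 nt (3'); the
    # extensions of the two inputs are mutually complementary (24 bp).
    new_strand("XOR1", c("x1", "t1*", "a1d", "y2*", "z")),
    new_strand("XOR2", c("y2", "t2*", "a2x", "a2y", "x1*", "z*")),
    # Erasable openers and their erasers (full complements with an extra
    # external toehold).
    new_strand("Is1", c("e1", "t1*", "a1d")),
    new_strand("Es1", c("a1d*", "t1", "e1*")),
    new_strand("Is2", c("e2", "t2*", "a2x", "a2y")),
    new_strand("Es2", c("a2y*", "a2x*", "t2", "e2*"))
  )
  names(strands) <- vapply(strands, `[[`, character(1), "name")

  lib <- structure(list(spec = spec, domains = domains, strands = strands),
                   class = "strand_library")
  validate_strand_library(lib)
  lib
}

validate_strand_library <- function(lib) {
  for (s in lib$strands) {
    unknown <- setdiff(dom_base(s$domains), names(lib$domains))
    if (length(unknown) > 0) {
      stop("strand ", s$name, " references unknown domains: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (!is.null(s$hairpin)) {
      arm1 <- vapply(s$hairpin, `[[`, integer(1), 1)
      arm2 <- vapply(s$hairpin, `[[`, integer(1), 2)
      if (length(intersect(arm1, arm2)) > 0) {
        stop("hairpin arms of ", s$name, " overlap", call. = FALSE)
      }
      ok <- vapply(s$hairpin, function(p) {
        dom_partner(s$domains[p[1]]) == s$domains[p[2]]
      }, logical(1))
      if (!all(ok)) {
        stop("hairpin arms of ", s$name, " are not mutually complementary",
             call. = FALSE)
      }
    }
  }
  invisible(lib)
}

#' Length of a canonical strand in nucleotides
#'
#' @param lib A strand library.
#' @param name Strand name, e.g. `"C1"`.
#' @return Integer length (sum of its domain lengths).
#' @export
strand_length <- function(lib, name) {
  s <- lib$strands[[name]]
  if (is.null(s)) stop("unknown strand: ", name, call. = FALSE)
  sum(vapply(s$domains, function(d) dom_len(lib, d), integer(1)))
}

#' @export
print.strand_library <- function(x, ...) {
  cat(sprintf("<strand_library> %d domains, %d strands\n",
              length(x$domains), length(x$strands)))
  for (s in x$strands) print(s)
  invisible(x)
}

#' Tabulate a strand library
#'
#' @param x A strand library.
#' @param ... Unused.
#' @return A tibble with one row per strand: name, 5'->3' domain layout,
#'   length in nt, and whether a hairpin is declared.
#' @export
tidy.strand_library <- function(x, ...) {
  tibble::tibble(
    strand = names(x$strands),
    domains = vapply(x$strands, function(s)
      paste(s$domains, collapse = " "), character(1)),
    length_nt = vapply(names(x$strands), function(n)
      as.integer(strand_length(x, n)), integer(1)),
    hairpin = vapply(x$strands, function(s) !is.null(s$hairpin), logical(1))
  )
}
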