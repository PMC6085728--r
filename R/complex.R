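#' @importFrom rlang .data
NULL

# A Complex is a set of strand instances plus a set of bound domain pairs
# (domain-level secondary structure). Bonds are rows (s1, p1, s2, p2):
# strand instance name + domain position on each side. `count` carries
# multiplicity of identical complexes; `inert` marks solution waste whose
# strands are wholly unavailable to the engine (sequestration rule).
new_complex <- function(strands, bonds = empty_bonds(), label = NA_character_,
                        count = 1L, inert = FALSE) {
  structure(list(strands = strands, bonds = bonds, label = label,
                 count = as.integer(count), inert = inert),
            class = "prism_complex")
}

empty_bonds <- function() {
  data.frame(s1 = character(0), p1 = integer(0),
             s2 = character(0), p2 = integer(0),
             stringsAsFactors = FALSE)
}

add_bond <- function(bonds, s1, p1, s2, p2) {
  # normalize endpoint order for stable keys
  if (s1 > s2 || (s1 == s2 && p1 > p2)) {
    tmp <- s1; s1 <- s2; s2 <- tmp
    tmp <- p1; p1 <- p2; p2 <- tmp
  }
  rbind(bonds, data.frame(s1 = s1, p1 = as.integer(p1),
                          s2 = s2, p2 = as.integer(p2),
                          stringsAsFactors = FALSE))
}

# Logical paired-map per strand instance.
paired_map <- function(cx) {
  pm <- lapply(cx$strands, function(s) rep(FALSE, length(s$domains)))
  b <- cx$bonds
  for (k in seq_len(nrow(b))) {
    pm[[b$s1[k]]][b$p1[k]] <- TRUE
    pm[[b$s2[k]]][b$p2[k]] <- TRUE
  }
  pm
}

# Bond rows touching a given (instance, position).
bonds_at <- function(cx, s, p) {
  which((cx$bonds$s1 == s & cx$bonds$p1 == p) |
          (cx$bonds$s2 == s & cx$bonds$p2 == p))
}

# Canonical key for complex identity (instance-name invariant).
complex_key <- function(cx) {
  species <- vapply(cx$strands, `[[`, character(1), "name")
  ord <- order(species, names(cx$strands))
  canon <- stats::setNames(paste0("S", seq_along(ord)), names(cx$strands)[ord])
  b <- cx$bonds
  if (nrow(b) > 0) {
    rows <- vapply(seq_len(nrow(b)), function(k) {
      e <- sort(c(paste0(canon[[b$s1[k]]], ":", b$p1[k]),
                  paste0(canon[[b$s2[k]]], ":", b$p2[k])))
      paste(e, collapse = "-")
    }, character(1))
    rows <- sort(rows)
  } else {
    rows <- character(0)
  }
  paste(paste(sort(species), collapse = ","), paste(rows, collapse = ";"),
        cx$inert, sep = "|")
}

# Split a complex into connected components (strands as nodes, bonds as
# edges; intramolecular bonds do not join anything new).
complex_components <- function(cx) {
  insts <- names(cx$strands)
  comp <- stats::setNames(seq_along(insts), insts)
  b <- cx$bonds
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(b))) {
      c1 <- comp[[b$s1[k]]]; c2 <- comp[[b$s2[k]]]
      if (c1 != c2) {
        comp[comp == max(c1, c2)] <- min(c1, c2)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(unique(comp), function(ci) {
    members <- insts[comp == ci]
    keep <- b$s1 %in% members & b$s2 %in% members
    new_complex(cx$strands[members], b[keep, , drop = FALSE],
                label = cx$label, count = cx$count, inert = cx$inert)
  })
}

validate_complex <- function(lib, cx) {
  pmseen <- list()
  b <- cx$bonds
  for (k in seq_len(nrow(b))) {
    d1 <- cx$strands[[b$s1[k]]]$domains[b$p1[k]]
    d2 <- cx$strands[[b$s2[k]]]$domains[b$p2[k]]
    if (dom_partner(d1) != d2) {
      stop("bond between non-complementary domains: ", d1, " / ", d2,
           call. = FALSE)
    }
    if (dom_len(lib, d1) != dom_len(lib, d2)) {
      stop("bonded domains of unequal length: ", d1, " / ", d2,
           call. = FALSE)
    }
    for (e in list(c(b$s1[k], b$p1[k]), c(b$s2[k], b$p2[k]))) {
      key <- paste(e, collapse = ":")
      if (!is.null(pmseen[[key]])) {
        stop("domain instance ", key, " participates in more than one bond",
             call. = FALSE)
      }
      pmseen[[key]] <- TRUE
    }
  }
  invisible(cx)
}

#' @export
print.prism_complex <- function(x, ...) {
  cat(sprintf("<prism_complex> %s: %d strand(s), %d bond(s)%s%s\n",
              if (is.na(x$label)) "(unlabelled)" else x$label,
              length(x$strands), nrow(x$bonds),
              if (x$count > 1) sprintf(", x%d", x$count) else "",
              if (x$inert) ", inert" else ""))
  invisible(x)
}

#' Assemble a triangular face motif
#'
#' Builds one of the two rigid equilateral faces as a connected complex of
#' four strands: the central strand plus three shorts, each side fully
#' paired over one 21-bp duplex domain, leaving three unpaired
#' single-stranded tails at the vertices (10 nt on face A, 16 nt on face B).
#' The central strand is cyclized by hybridization along all three sides;
#' its two ends meet at a backbone nick in the middle of the side carrying
#' the second short strand (where the dye or quencher is attached).
#'
#' @param lib A strand library.
#' @param face `"A"` or `"B"`.
#' @return A `prism_complex` labelled `faceA` or `faceB`.
#' @export
assemble_face <- function(lib, face = c("A", "B")) {
  face <- match.arg(face)
  central <- paste0("L", face)
  shorts <- paste0(face, 1:3)
  needed <- c(central, shorts)
  missing <- setdiff(needed, names(lib$strands))
  if (length(missing) > 0) {
    stop("assembly error: missing strand(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  strands <- lib$strands[needed]
  bonds <- empty_bonds()
  for (i in 1:3) {
    # side i: central-strand face domain pairs the short strand's first
    # domain (its face-side complement)
    bonds <- add_bond(bonds, central, i, shorts[i], 1L)
  }
  cx <- new_complex(strands, bonds, label = paste0("face", face))
  validate_complex(lib, cx)
  cx
}

#' Assemble the closed triangular prism
#'
#' Hetero-dimerizes face A and face B by hybridizing their vertex tails:
#' each of the three vertical edges is a 10-bp duplex between an A tail and
#' the stem part of the matching 16-nt B tail, leaving a free 6-nt toehold
#' on each B strand. The result is a single connected complex of 8 strands
#' in the closed state.
#'
#' @param lib A strand library.
#' @param faceA,faceB Complexes from [assemble_face()].
#' @return A `prism_complex` labelled `prism`.
#' @examples
#' lib <- build_canonical_strands(architecture_spec())
#' prism <- assemble_prism(lib, assemble_face(lib, "A"), assemble_face(lib, "B"))
#' prism_state(prism)
#' @export
assemble_prism <- function(lib, faceA = assemble_face(lib, "A"),
                           faceB = assemble_face(lib, "B")) {
  for (cx in list(faceA, faceB)) {
    if (!inherits(cx, "prism_complex")) {
      stop("assembly error: faces must be prism_complex objects",
           call. = FALSE)
    }
  }
  strands <- c(faceA$strands, faceB$strands)
  needed <- c("LA", "A1", "A2", "A3", "LB", "B1", "B2", "B3")
  missing <- setdiff(needed, names(strands))
  if (length(missing) > 0) {
    stop("assembly error: missing strand(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bonds <- rbind(faceA$bonds, faceB$bonds)
  for (i in 1:3) {
    ai <- paste0("A", i); bi <- paste0("B", i)
    da <- strands[[ai]]$domains
    db <- strands[[bi]]$domains
    used <- logical(length(db))
    n_edge <- 0L
    for (p in seq_along(da)[-1]) {   # skip the face-side domain
      q <- which(db == dom_partner(da[p]) & !used)
      if (length(q) >= 1) {
        bonds <- add_bond(bonds, ai, p, bi, q[1])
        used[q[1]] <- TRUE
        n_edge <- n_edge + 1L
      }
    }
    if (n_edge == 0L) {
      stop("assembly error: tail mismatch on edge ", i, call. = FALSE)
    }
  }
  cx <- new_complex(strands, bonds, label = "prism")
  validate_complex(lib, cx)
  cx
}

#' Structural state of the prism
#'
#' Classifies a prism-derived configuration: which of the three vertical
#' edges have been displaced (an edge is open iff no A-tail/B-tail bond
#' remains on it) and whether the two face motifs are still joined by at
#' least one edge. The eight canonical states are `closed`, the three
#' `mono-SD(Ci)`, the three `di-SD(Ci/Cj)` and the dissociated
#' `tri-SD(C1/C2/C3)`.
#'
#' @param x A `prism_complex`, a list of complexes, or a reaction system.
#' @return An object of class `prism_state` with fields `opened_edges`,
#'   `connected` and `label`.
#' @export
prism_state <- function(x) {
  complexes <- if (inherits(x, "prism_complex")) list(x)
  else if (inherits(x, "reaction_system")) x$complexes
  else x
  species_of <- function(cx) vapply(cx$strands, `[[`, character(1), "name")
  host <- function(sp) {
    idx <- which(vapply(complexes, function(cx) sp %in% species_of(cx),
                        logical(1)))
    if (length(idx) != 1) {
      stop("classification error: complex is not prism-derived (strand ",
           sp, " found in ", length(idx), " complexes)", call. = FALSE)
    }
    idx
  }
  idx_needed <- vapply(c("LA", "LB", paste0("A", 1:3), paste0("B", 1:3)),
                       host, integer(1))
  opened <- integer(0)
  for (i in 1:3) {
    ai <- paste0("A", i); bi <- paste0("B", i)
    cxa <- complexes[[idx_needed[[ai]]]]
    sp <- species_of(cxa)
    edge_bond <- FALSE
    if (bi %in% sp) {
      ia <- names(cxa$strands)[sp == ai][1]
      ib <- names(cxa$strands)[sp == bi][1]
      b <- cxa$bonds
      edge_bond <- any((b$s1 == ia & b$s2 == ib) | (b$s1 == ib & b$s2 == ia))
    }
    if (!edge_bond) opened <- c(opened, i)
  }
  connected <- idx_needed[["LA"]] == idx_needed[["LB"]]
  label <- if (length(opened) == 0) "closed"
  else if (length(opened) == 1) sprintf("mono-SD(C%d)", opened)
  else if (length(opened) == 2) sprintf("di-SD(C%d/C%d)", opened[1], opened[2])
  else "tri-SD(C1/C2/C3)"
  structure(list(opened_edges = opened, connected = connected, label = label),
            class = "prism_state")
}

#' @export
print.prism_state <- function(x, ...) {
  cat(sprintf("<prism_state> %s (opened edges: %s; faces %s)\n", x$label,
              if (length(x$opened_edges) == 0) "none"
              else paste(x$opened_edges, collapse = ","),
              if (x$connected) "connected" else "dissociated"))
  invisible(x)
}

#' Bond list of a complex as a tibble
#'
#' A graph edge-list view for serialization or visualization: one row per
#' bond with strand instances, domain positions and domain names.
#'
#' @param cx A `prism_complex`.
#' @return A tibble.
#' @export
complex_edgelist <- function(cx) {
  b <- cx$bonds
  tibble::tibble(
    s1 = b$s1, p1 = b$p1,
    d1 = vapply(seq_len(nrow(b)), function(k)
      cx$strands[[b$s1[k]]]$domains[b$p1[k]], character(1)),
    s2 = b$s2, p2 = b$p2,
    d2 = vapply(seq_len(nrow(b)), function(k)
      cx$strands[[b$s2[k]]]$domains[b$p2[k]], character(1))
  )
}

#' Serialize a complex to a human-readable structure file
#'
#' @param cx A `prism_complex`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_complex_text <- function(cx, path) {
  lines <- c(
    sprintf("complex %s count %d%s",
            if (is.na(cx$label)) "-" else cx$label, cx$count,
            if (cx$inert) " inert" else ""),
    "strands:",
    vapply(names(cx$strands), function(inst) {
      s <- cx$strands[[inst]]
      sprintf("  %s (%s): 5'-[%s]-3'", inst, s$name,
              paste(s$domains, collapse = " "))
    }, character(1)),
    "bonds:"
  )
  el <- complex_edgelist(cx)
  lines <- c(lines, vapply(seq_len(nrow(el)), function(k)
    sprintf("  %s:%d (%s) = %s:%d (%s)", el$s1[k], el$p1[k], el$d1[k],
            el$s2[k], el$p2[k], el$d2[k]), character(1)))
  writeLines(lines, path)
  invisible(path)
}
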