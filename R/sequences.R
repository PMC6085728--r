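#' Reverse complement of a DNA string
#'
#' @param x A character string over `A`, `C`, `G`, `T`.
#' @return The reverse complement, 5'->3'.
#' @examples
#' dna_revcomp("ACGTAC")
#' @export
dna_revcomp <- function(x) {
  check_dna(x)
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(s)), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

check_dna <- function(x) {
  if (!all(grepl("^[ACGTacgt]*$", x))) {
    stop("sequences must be over the alphabet {A,C,G,T}", call. = FALSE)
  }
  invisible(x)
}

#' Longest complementary stretch between two sequences
#'
#' Length of the longest contiguous run of `s1` that is reverse-complementary
#' to a contiguous run of `s2` (i.e. the two runs could form an antiparallel
#' Watson-Crick duplex). Equivalently, the longest common substring of `s1`
#' and the reverse complement of `s2`.
#'
#' @param s1,s2 DNA strings over `A`, `C`, `G`, `T`.
#' @return Integer stretch length (0 if no base of `s1` can pair with `s2`).
#' @examples
#' max_complementary_stretch("AAAA", "TTTT")  # 4
#' max_complementary_stretch("AAAA", "AAAA")  # 0: A does not pair with A
#' @export
max_complementary_stretch <- function(s1, s2) {
  check_dna(s1); check_dna(s2)
  if (nchar(s1) == 0 || nchar(s2) == 0) return(0L)
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(dna_revcomp(s2), "")[[1]]
  n <- length(a)
  prev <- integer(n)
  best <- 0L
  for (j in seq_along(b)) {
    shifted <- c(0L, prev[-n])
    cur <- integer(n)
    hit <- a == b[j]
    cur[hit] <- shifted[hit] + 1L
    best <- max(best, cur)
    prev <- cur
  }
  as.integer(best)
}

# Longest intended (by-design) antiparallel duplex run between two domain
# lists, in nucleotides: maximal co-linear run of Watson-Crick partner
# domains.
intended_stretch <- function(lib, d1, d2) {
  best <- 0L
  for (i in seq_along(d1)) {
    for (j in seq_along(d2)) {
      if (dom_partner(d1[i]) == d2[j]) {
        run <- 0L
        k <- 0L
        while (i + k <= length(d1) && j - k >= 1 &&
               dom_partner(d1[i + k]) == d2[j - k]) {
          run <- run + dom_len(lib, d1[i + k])
          k <- k + 1L
        }
        best <- max(best, run)
      }
    }
  }
  best
}

sample_domain_seq <- function(len, gc, max_homopolymer, tries = 500) {
  for (i in seq_len(tries)) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    chars <- strsplit(s, "")[[1]]
    if (max(rle(chars)$lengths) > max_homopolymer) next
    if (len >= 5) {
      frac <- mean(chars %in% c("G", "C"))
      if (frac < gc[1] || frac > gc[2]) next
    }
    return(s)
  }
  NULL
}

#' Generate a concrete sequence assignment for the strand library
#'
#' Assigns random nucleotides to every base domain under conventional design
#' hygiene (GC fraction window, bounded homopolymer runs) and an
#' orthogonality constraint: between any two non-partner domains, in either
#' orientation, the longest complementary stretch is at most `max_stretch`
#' nt (default 5, strictly below the 6-nt functional toehold, so no
#' unintended toehold-mediated reaction can initiate in the engine's own
#' semantics). A second audit is enforced on every pair of single-stranded
#' functional elements (input strands and vertex tails - the regions that
#' are ever single-stranded and hence reactive), allowing each pair its
#' intended duplex run plus `max_stretch` nt of chance junction extension.
#'
#' Generation is deterministic for a fixed seed and retries whole
#' assignments until the audit passes.
#'
#' @param lib A strand library.
#' @param seed Integer seed; the same seed always yields the same assignment.
#' @param gc Two-element GC-fraction window applied to domains of >= 5 nt.
#' @param max_stretch Orthogonality cap `k` in nt.
#' @param max_homopolymer Longest allowed single-base run.
#' @param max_tries Bound on whole-assignment attempts.
#' @return An object of class `prism_sequences`: base-domain sequences,
#'   full strand sequences, the audit table, and the generation parameters.
#' @examples
#' lib <- build_canonical_strands(architecture_spec())
#' seqs <- generate_sequences(lib, seed = 1)
#' nchar(seqs$strand_seqs[["C1"]])  # 16
#' @export
generate_sequences <- function(lib, seed, gc = c(0.40, 0.60),
                               max_stretch = 5, max_homopolymer = 4,
                               max_tries = 60) {
  stopifnot(inherits(lib, "strand_library"))
  if (missing(seed) || !is.numeric(seed)) {
    stop("a numeric seed is required for reproducible generation",
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    last_violation <- NULL
    for (attempt in seq_len(max_tries)) {
      assign <- try_assignment(lib, gc, max_stretch, max_homopolymer)
      if (is.null(assign)) {
        last_violation <- "no domain assignment satisfied the pairwise cap"
        next
      }
      strand_seqs <- strand_sequences(lib, assign)
      audit <- orthogonality_audit_impl(lib, assign, strand_seqs, max_stretch)
      if (all(audit$ok)) {
        return(structure(list(
          domain_seqs = assign, strand_seqs = strand_seqs,
          audit = audit, seed = as.integer(seed),
          params = list(gc = gc, max_stretch = max_stretch,
                        max_homopolymer = max_homopolymer)
        ), class = "prism_sequences"))
      }
      bad <- audit[!audit$ok, ][1, ]
      last_violation <- sprintf("%s vs %s: stretch %d > allowed %d",
                                bad$a, bad$b, bad$observed, bad$allowed)
    }
    stop("sequence generation failed after ", max_tries,
         " attempts; last violated constraint: ", last_violation,
         call. = FALSE)
  })
}

# One whole-assignment attempt at the domain level; NULL on failure.
try_assignment <- function(lib, gc, max_stretch, max_homopolymer) {
  doms <- names(sort(lib$domains, decreasing = TRUE))
  assign <- character(0)
  for (d in doms) {
    len <- lib$domains[[d]]
    ok_seq <- NULL
    for (i in seq_len(200)) {
      s <- sample_domain_seq(len, gc, max_homopolymer)
      if (is.null(s)) break
      # Self-complementarity, then both orientations against every
      # previously assigned domain (partner pairs are by construction the
      # derived complements and never enter this scan).
      if (max_complementary_stretch(s, s) > max_stretch) next
      clash <- FALSE
      for (q in assign) {
        if (max_complementary_stretch(s, q) > max_stretch ||
            lc_substring(s, q) > max_stretch) {
          clash <- TRUE
          break
        }
      }
      if (!clash) {
        ok_seq <- s
        break
      }
    }
    if (is.null(ok_seq)) return(NULL)
    assign[[d]] <- ok_seq
  }
  assign
}

# Longest common (equal-orientation) substring; equals the complementary
# stretch between s1 and the complement of s2.
lc_substring <- function(s1, s2) {
  max_complementary_stretch(s1, dna_revcomp(s2))
}

strand_sequences <- function(lib, domain_seqs) {
  seq_of <- function(d) {
    if (dom_is_comp(d)) dna_revcomp(domain_seqs[[dom_base(d)]])
    else domain_seqs[[dom_base(d)]]
  }
  vapply(lib$strands, function(s) {
    paste(vapply(s$domains, seq_of, character(1)), collapse = "")
  }, character(1))
}

# Single-stranded functional elements of the architecture: the input
# strands in full, plus the vertex tails of the face short strands. The
# 21-bp face sides and the central strands are permanently duplexed in
# every complex the engine can reach, so spurious complementarity there
# can never initiate a reaction and is not constrained.
ss_elements <- function(lib) {
  face <- c("LA", "LB", paste0("A", 1:3), paste0("B", 1:3))
  els <- list()
  for (nm in setdiff(names(lib$strands), face)) {
    els[[nm]] <- lib$strands[[nm]]$domains
  }
  for (nm in c(paste0("A", 1:3), paste0("B", 1:3))) {
    els[[paste0(nm, "-tail")]] <- lib$strands[[nm]]$domains[-1]
  }
  els
}

orthogonality_audit_impl <- function(lib, domain_seqs, strand_seqs,
                                     max_stretch) {
  doms <- names(lib$domains)
  rows <- list()
  for (i in seq_along(doms)) {
    for (j in i:length(doms)) {
      a <- doms[i]; b <- doms[j]
      # For a != b both orientations are non-partner pairs; on the diagonal
      # only self-complementarity applies (d vs d* is the intended partner).
      obs <- max_complementary_stretch(domain_seqs[[a]], domain_seqs[[b]])
      if (a != b) {
        obs <- max(obs, lc_substring(domain_seqs[[a]], domain_seqs[[b]]))
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        level = "domain", a = a, b = b,
        observed = obs, allowed = as.integer(max_stretch))
    }
  }
  els <- ss_elements(lib)
  seq_of_element <- function(domains) {
    paste(vapply(domains, function(d) {
      if (dom_is_comp(d)) dna_revcomp(domain_seqs[[dom_base(d)]])
      else domain_seqs[[dom_base(d)]]
    }, character(1)), collapse = "")
  }
  eseqs <- vapply(els, seq_of_element, character(1))
  enames <- names(els)
  for (i in seq_along(enames)) {
    for (j in i:length(enames)) {
      a <- enames[i]; b <- enames[j]
      intended <- intended_stretch(lib, els[[a]], els[[b]])
      allowed <- if (intended > 0) intended + max_stretch else max_stretch
      rows[[length(rows) + 1]] <- tibble::tibble(
        level = "element", a = a, b = b,
        observed = max_complementary_stretch(eseqs[[a]], eseqs[[b]]),
        allowed = as.integer(allowed))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$ok <- out$observed <= out$allowed
  out
}

#' Audit a sequence assignment for orthogonality
#'
#' Recomputes the full audit of [generate_sequences()]: every pair of
#' non-partner domains (both orientations) must stay at or below the cap,
#' and every pair of single-stranded functional elements (input strands,
#' vertex tails) at or below its intended duplex run plus the cap.
#'
#' @param lib A strand library.
#' @param seqs A `prism_sequences` object.
#' @param max_stretch Orthogonality cap in nt.
#' @return A tibble with columns `level`, `a`, `b`, `observed`, `allowed`,
#'   `ok`.
#' @export
orthogonality_audit <- function(lib, seqs, max_stretch = 5) {
  stopifnot(inherits(seqs, "prism_sequences"))
  orthogonality_audit_impl(lib, seqs$domain_seqs, seqs$strand_seqs,
                           max_stretch)
}

#' @export
print.prism_sequences <- function(x, ...) {
  cat(sprintf("<prism_sequences> seed %d: %d domains, %d strands, audit %s\n",
              x$seed, length(x$domain_seqs), length(x$strand_seqs),
              if (all(x$audit$ok)) "pass" else "FAIL"))
  invisible(x)
}

#' @rdname generate_sequences
#' @param x A `prism_sequences` object.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per strand (name, sequence,
#'   length).
#' @export
tidy.prism_sequences <- function(x, ...) {
  tibble::tibble(
    strand = names(x$strand_seqs),
    sequence = unname(x$strand_seqs),
    length_nt = nchar(unname(x$strand_seqs))
  )
}

#' Write / read strand sequences as FASTA
#'
#' One record per strand; record names are strand names. Writing is
#' byte-deterministic for a fixed sequence assignment.
#'
#' @param seqs A `prism_sequences` object.
#' @param path Output (or input) FASTA path.
#' @return `write_strand_fasta()` returns `path` invisibly;
#'   `read_strand_fasta()` returns a named character vector of sequences.
#' @export
write_strand_fasta <- function(seqs, path) {
  stopifnot(inherits(seqs, "prism_sequences"))
  set <- Biostrings::DNAStringSet(seqs$strand_seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' @rdname write_strand_fasta
#' @export
read_strand_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}
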