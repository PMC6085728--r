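#' Engine parameters
#'
#' Deterministic endpoint semantics: no rate constants, no stochastic
#' simulation. `min_toehold` is the smallest single-stranded stretch that
#' can nucleate a displacement (2 nt, the extra toehold of the AND-gate
#' activator). `input_excess` is the input:prism stoichiometry (5x, i.e.
#' 165 nM inputs against the 33 nM prism); input-input sequestration
#' annihilates equimolar partners completely.
#'
#' @param min_toehold Minimum toehold length in nt.
#' @param input_excess Copies of each input strand added per prism.
#' @param max_iter Iteration cap of [react_to_fixed_point()] (termination
#'   guard; every step strictly increases total pairing or consumes a free
#'   invader, so the cap is never reached on well-formed systems).
#' @return A list of engine parameters.
#' @export
engine_params <- function(min_toehold = 2, input_excess = 5, max_iter = 400) {
  stopifnot(min_toehold >= 1, input_excess >= 1, max_iter >= 1)
  list(min_toehold = as.integer(min_toehold),
       input_excess = as.integer(input_excess),
       max_iter = as.integer(max_iter))
}

#' Create a reaction system
#'
#' A reaction system holds the complexes (prism, folded hairpins, waste
#' duplexes), the multiset of free strands, the engine parameters and an
#' ordered trace of applied reactions. Total strand count is conserved
#' across every reaction step.
#'
#' @param lib A strand library.
#' @param complexes List of `prism_complex` objects (e.g. the assembled
#'   prism).
#' @param free Free strands: a character vector of species names (each
#'   added at `input_excess` copies) or a named integer vector of counts.
#' @param params Engine parameters from [engine_params()].
#' @return An object of class `reaction_system`.
#' @export
reaction_system <- function(lib, complexes = list(), free = character(0),
                            params = engine_params()) {
  stopifnot(inherits(lib, "strand_library"))
  counts <- stats::setNames(integer(0), character(0))
  sys <- structure(list(lib = lib, complexes = list(), free = counts,
                        params = params, trace = list()),
                   class = "reaction_system")
  for (cx in complexes) sys <- sys_merge_complex(sys, cx)
  sys <- add_inputs(sys, free)
  sys
}

#' Add free input strands to a system
#'
#' @param sys A reaction system.
#' @param free Species names (character vector, each at `input_excess`
#'   copies) or a named count vector.
#' @return The updated system.
#' @export
add_inputs <- function(sys, free) {
  if (length(free) == 0) return(sys)
  if (is.null(names(free))) {
    free <- stats::setNames(rep(sys$params$input_excess, length(free)), free)
  }
  unknown <- setdiff(names(free), names(sys$lib$strands))
  if (length(unknown) > 0) {
    stop("unknown strand species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(free)) {
    cur <- if (nm %in% names(sys$free)) sys$free[[nm]] else 0L
    sys$free[[nm]] <- cur + as.integer(free[[nm]])
  }
  sys
}

sys_merge_complex <- function(sys, cx) {
  key <- complex_key(cx)
  for (i in seq_along(sys$complexes)) {
    if (complex_key(sys$complexes[[i]]) == key) {
      sys$complexes[[i]]$count <- sys$complexes[[i]]$count + cx$count
      return(sys)
    }
  }
  sys$complexes[[length(sys$complexes) + 1]] <- cx
  sys
}

sys_trace <- function(sys, rule, reactants, products, pairing_gain = 0L,
                      note = NULL) {
  sys$trace[[length(sys$trace) + 1]] <- list(
    rule = rule, reactants = reactants, products = products,
    pairing_gain = as.integer(pairing_gain), note = note)
  sys
}

# Multiset of strand species over the whole system (conservation checks).
strand_census <- function(sys) {
  tally <- sys$free[sys$free > 0]
  for (cx in sys$complexes) {
    for (s in cx$strands) {
      cur <- if (s$name %in% names(tally)) tally[[s$name]] else 0L
      tally[[s$name]] <- cur + cx$count
    }
  }
  tally <- tally[tally > 0]
  tally[order(names(tally))]
}

system_key <- function(sys) {
  ck <- sort(vapply(sys$complexes, function(cx)
    paste0(complex_key(cx), "x", cx$count), character(1)))
  fr <- sys$free[sys$free > 0]
  fr <- fr[order(names(fr))]
  paste(paste(ck, collapse = "&"),
        paste(names(fr), fr, sep = "=", collapse = ","), sep = "||")
}

#' Fold declared hairpins among free strands
#'
#' Every free strand carrying a hairpin declaration is folded into a
#' single-strand complex whose stem bonds cage the enclosed domains,
#' making them unavailable for intermolecular initiation until an invader
#' opens the stem through the adjacent toehold.
#'
#' @param sys A reaction system.
#' @return The updated system (a no-op when no foldable strands are free).
#' @export
fold_hairpins <- function(sys) {
  for (nm in names(sys$free)) {
    n <- sys$free[[nm]]
    s <- sys$lib$strands[[nm]]
    if (n > 0 && !is.null(s$hairpin)) {
      bonds <- empty_bonds()
      for (p in s$hairpin) bonds <- add_bond(bonds, nm, p[1], nm, p[2])
      cx <- new_complex(stats::setNames(list(s), nm), bonds,
                        label = paste0(nm, "-folded"), count = n)
      sys$free[[nm]] <- 0L
      sys <- sys_merge_complex(sys, cx)
      sys <- sys_trace(sys, "fold", nm, paste0(nm, "-folded"),
                       pairing_gain = sum(vapply(s$hairpin, function(p)
                         dom_len(sys$lib, s$domains[p[1]]), integer(1))) * n)
    }
  }
  sys
}

# Greedy maximum pairing between two free strands: complementary domain
# instances matched one-to-one, longest domains first.
greedy_pairing <- function(lib, sA, sB) {
  dA <- sA$domains; dB <- sB$domains
  cand <- list()
  for (i in seq_along(dA)) {
    for (j in seq_along(dB)) {
      if (dom_partner(dA[i]) == dB[j]) {
        cand[[length(cand) + 1]] <- c(i, j, dom_len(lib, dA[i]))
      }
    }
  }
  if (length(cand) == 0) return(list(gain = 0L, pairs = list()))
  m <- do.call(rbind, cand)
  m <- m[order(-m[, 3], m[, 1], m[, 2]), , drop = FALSE]
  usedA <- logical(length(dA)); usedB <- logical(length(dB))
  pairs <- list(); gain <- 0L
  for (k in seq_len(nrow(m))) {
    i <- m[k, 1]; j <- m[k, 2]
    if (!usedA[i] && !usedB[j]) {
      usedA[i] <- TRUE; usedB[j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(i, j)
      gain <- gain + m[k, 3]
    }
  }
  list(gain = as.integer(gain), pairs = pairs)
}

#' Resolve solution-phase hybridization among free strands
#'
#' Greedily forms duplexes among free strands in descending order of
#' pairing gain (ties broken by lexicographic species names). Equimolar
#' partners annihilate pairwise into inert waste duplexes; a strand
#' captured in a solution duplex is wholly inert toward complexes, which
#' is the mechanism behind the INHIBIT and XOR gates.
#'
#' @param sys A reaction system.
#' @return The updated system.
#' @export
resolve_solution_hybridization <- function(sys) {
  repeat {
    species <- sort(names(sys$free)[sys$free > 0])
    if (length(species) < 2) break
    best <- NULL
    for (i in seq_along(species)) {
      for (j in seq_along(species)) {
        if (j <= i) next
        a <- species[i]; b <- species[j]
        pr <- greedy_pairing(sys$lib, sys$lib$strands[[a]],
                             sys$lib$strands[[b]])
        if (pr$gain >= sys$params$min_toehold &&
            (is.null(best) || pr$gain > best$gain)) {
          best <- list(a = a, b = b, gain = pr$gain, pairs = pr$pairs)
        }
      }
    }
    if (is.null(best)) break
    n <- min(sys$free[[best$a]], sys$free[[best$b]])
    sys$free[[best$a]] <- sys$free[[best$a]] - n
    sys$free[[best$b]] <- sys$free[[best$b]] - n
    bonds <- empty_bonds()
    for (p in best$pairs) bonds <- add_bond(bonds, best$a, p[1], best$b, p[2])
    waste <- new_complex(
      stats::setNames(sys$lib$strands[c(best$a, best$b)],
                      c(best$a, best$b)),
      bonds, label = paste0("waste(", best$a, ":", best$b, ")"),
      count = n, inert = TRUE)
    sys <- sys_merge_complex(sys, waste)
    sys <- sys_trace(sys, "sequester", c(best$a, best$b), waste$label,
                     pairing_gain = best$gain * n)
  }
  sys
}

# Maximal unpaired runs of a strand instance within a complex.
free_runs <- function(cx, inst, pm = paired_map(cx)) {
  p <- pm[[inst]]
  runs <- list()
  i <- 1
  while (i <= length(p)) {
    if (!p[i]) {
      j <- i
      while (j < length(p) && !p[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- i:j
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

# All candidate displacement sites on strand `inst` of complex `cx`:
# a contiguous stretch whose outer block is an unpaired toehold of at
# least min_toehold nt and whose inner block is paired, such that every
# incumbent strand touched loses *all* of its bonds to the target strand
# (complete branch-migration; partial displacement is not modelled).
target_sites <- function(lib, cx, inst, min_toehold) {
  s <- cx$strands[[inst]]
  pm <- paired_map(cx)
  pT <- pm[[inst]]
  n <- length(pT)
  lens <- vapply(s$domains, function(d) dom_len(lib, d), integer(1))
  sites <- list()

  boundary_ok <- function(displ) {
    rows_displ <- unlist(lapply(displ, function(p) bonds_at(cx, inst, p)))
    incumbents <- unique(unlist(lapply(rows_displ, function(k) {
      ends <- c(cx$bonds$s1[k], cx$bonds$s2[k])
      setdiff(ends, inst) -> other
      if (length(other) == 0) inst else other   # intramolecular: self
    })))
    for (inc in incumbents) {
      if (inc == inst) {
        rows_inc <- which(cx$bonds$s1 == inst & cx$bonds$s2 == inst)
      } else {
        rows_inc <- which((cx$bonds$s1 == inst & cx$bonds$s2 == inc) |
                            (cx$bonds$s1 == inc & cx$bonds$s2 == inst))
      }
      if (!all(rows_inc %in% rows_displ)) return(FALSE)
    }
    TRUE
  }

  push_site <- function(site, toehold_nt, displ) {
    sites[[length(sites) + 1]] <<- list(
      positions = site, toehold_nt = toehold_nt, displaced = displ,
      formed_nt = sum(lens[site]), broken_nt = sum(lens[displ]))
  }

  for (k in seq_len(n)) {
    if (pT[k]) next
    # toehold block left of the duplex
    if (k < n && pT[k + 1]) {
      u1 <- k
      while (u1 > 1 && !pT[u1 - 1]) u1 <- u1 - 1
      q2 <- k + 1
      while (q2 < n && pT[q2 + 1]) q2 <- q2 + 1
      for (t_start in u1:k) {
        toe <- sum(lens[t_start:k])
        if (toe < min_toehold) next
        for (e in seq_len(q2 - k)) {
          displ <- (k + 1):(k + e)
          if (!boundary_ok(displ)) next
          push_site(t_start:(k + e), toe, displ)
        }
      }
    }
    # toehold block right of the duplex
    if (k > 1 && pT[k - 1]) {
      u2 <- k
      while (u2 < n && !pT[u2 + 1]) u2 <- u2 + 1
      q1 <- k - 1
      while (q1 > 1 && pT[q1 - 1]) q1 <- q1 - 1
      for (t_end in k:u2) {
        toe <- sum(lens[k:t_end])
        if (toe < min_toehold) next
        for (e in seq_len(k - q1)) {
          displ <- (k - e):(k - 1)
          if (!boundary_ok(displ)) next
          push_site((k - e):t_end, toe, displ)
        }
      }
    }
  }
  sites
}

# Does `run` (a free contiguous stretch of invader domains, 5'->3')
# contain `needed` as a contiguous window? Returns start offset or NA.
window_match <- function(run_domains, needed) {
  nr <- length(run_domains); nn <- length(needed)
  if (nn > nr) return(NA_integer_)
  for (off in 0:(nr - nn)) {
    if (all(run_domains[off + seq_len(nn)] == needed)) return(off + 1L)
  }
  NA_integer_
}

#' Enumerate applicable toehold-mediated invasions
#'
#' Lists every reaction in which a free, uncaged strand segment
#' complementary to an exposed unpaired stretch of at least `min_toehold`
#' nt on a complex can bind and, by branch migration, fully displace the
#' incumbent pairing it abuts. Invaders may be free strands or free
#' segments of strands already held in (non-inert) complexes, e.g. the
#' released C2 block of an activated hairpin. The list is deterministic:
#' descending pairing gain, then nucleotides formed, then lexicographic
#' reactant names.
#'
#' @param sys A reaction system.
#' @return A list of invasion descriptors (possibly empty).
#' @export
enumerate_invasions <- function(sys) {
  lib <- sys$lib
  invaders <- list()
  for (nm in sort(names(sys$free)[sys$free > 0])) {
    s <- lib$strands[[nm]]
    invaders[[length(invaders) + 1]] <- list(
      kind = "free", species = nm, inst = nm, ci = NA_integer_,
      runs = list(seq_along(s$domains)), domains = s$domains)
  }
  for (ci in seq_along(sys$complexes)) {
    cx <- sys$complexes[[ci]]
    if (cx$inert) next
    pm <- paired_map(cx)
    for (inst in names(cx$strands)) {
      runs <- free_runs(cx, inst, pm)
      if (length(runs) > 0) {
        invaders[[length(invaders) + 1]] <- list(
          kind = "complex", species = cx$strands[[inst]]$name, inst = inst,
          ci = ci, runs = runs, domains = cx$strands[[inst]]$domains)
      }
    }
  }

  out <- list()
  for (ci in seq_along(sys$complexes)) {
    cx <- sys$complexes[[ci]]
    if (cx$inert) next
    for (inst in names(cx$strands)) {
      sites <- target_sites(lib, cx, inst, sys$params$min_toehold)
      if (length(sites) == 0) next
      tdoms <- cx$strands[[inst]]$domains
      for (site in sites) {
        needed <- dom_partner(rev(tdoms[site$positions]))
        for (inv in invaders) {
          if (!is.na(inv$ci) && inv$ci == ci) next   # same complex: skip
          if (inv$kind == "complex" && inv$inst == inst) next
          for (run in inv$runs) {
            off <- window_match(inv$domains[run], needed)
            if (!is.na(off)) {
              out[[length(out) + 1]] <- list(
                rule = "invade",
                invader_kind = inv$kind, invader_species = inv$species,
                invader_inst = inv$inst, invader_ci = inv$ci,
                invader_positions = run[off + seq_along(needed) - 1L],
                target_ci = ci, target_inst = inst,
                site = site$positions, displaced = site$displaced,
                toehold_nt = site$toehold_nt,
                formed_nt = site$formed_nt, broken_nt = site$broken_nt,
                pairing_gain = site$formed_nt - site$broken_nt)
              break
            }
          }
        }
      }
    }
  }
  if (length(out) == 0) return(out)
  key <- vapply(out, function(r) paste(
    r$invader_species, r$invader_inst, r$invader_ci, r$target_ci,
    r$target_inst, min(r$site), sep = "|"), character(1))
  ord <- order(-vapply(out, `[[`, integer(1), "pairing_gain"),
               -vapply(out, `[[`, integer(1), "formed_nt"),
               vapply(out, `[[`, character(1), "invader_species"),
               vapply(out, `[[`, character(1), "target_inst"),
               key)
  out <- out[ord]
  out[!duplicated(key[ord])]
}

unique_inst <- function(existing, species) {
  nm <- species
  k <- 1
  while (nm %in% existing) {
    k <- k + 1
    nm <- paste0(species, "#", k)
  }
  nm
}

# Pop one unit of complex `ci` out of the system; returns list(sys, cx).
pop_complex_unit <- function(sys, ci) {
  cx <- sys$complexes[[ci]]
  if (cx$count > 1) {
    sys$complexes[[ci]]$count <- cx$count - 1L
    cx$count <- 1L
  } else {
    sys$complexes[[ci]] <- NULL
  }
  list(sys = sys, cx = cx)
}

apply_invasion <- function(sys, r) {
  # pop target first (indices shift if invader complex comes earlier)
  inv_cx <- NULL
  if (r$invader_kind == "complex") {
    kt <- complex_key(sys$complexes[[r$target_ci]])
    ki <- complex_key(sys$complexes[[r$invader_ci]])
    pop <- pop_complex_unit(sys, r$target_ci)
    sys <- pop$sys; target <- pop$cx
    ici <- which(vapply(sys$complexes, function(c) complex_key(c) == ki,
                        logical(1)))[1]
    pop <- pop_complex_unit(sys, ici)
    sys <- pop$sys; inv_cx <- pop$cx
  } else {
    pop <- pop_complex_unit(sys, r$target_ci)
    sys <- pop$sys; target <- pop$cx
  }

  if (r$invader_kind == "free") {
    sys$free[[r$invader_species]] <- sys$free[[r$invader_species]] - 1L
    inv_inst <- unique_inst(names(target$strands), r$invader_species)
    target$strands[[inv_inst]] <- sys$lib$strands[[r$invader_species]]
    merged <- target
  } else {
    newnames <- character(0)
    for (old in names(inv_cx$strands)) {
      newnames <- c(newnames, unique_inst(c(names(target$strands), newnames),
                                          old))
    }
    rename <- stats::setNames(newnames, names(inv_cx$strands))
    strands <- c(target$strands,
                 stats::setNames(inv_cx$strands, unname(rename)))
    b2 <- inv_cx$bonds
    if (nrow(b2) > 0) {
      b2$s1 <- unname(rename[b2$s1])
      b2$s2 <- unname(rename[b2$s2])
    }
    merged <- new_complex(strands, rbind(target$bonds, b2),
                          label = target$label)
    inv_inst <- unname(rename[[r$invader_inst]])
  }

  # break displaced bonds
  drop_rows <- unlist(lapply(r$displaced, function(p)
    bonds_at(merged, r$target_inst, p)))
  if (length(drop_rows) > 0) {
    merged$bonds <- merged$bonds[-unique(drop_rows), , drop = FALSE]
  }
  # form site bonds: invader window position w_i pairs site position
  # (reversed; antiparallel)
  site <- r$site
  invp <- r$invader_positions
  for (idx in seq_along(invp)) {
    merged$bonds <- add_bond(merged$bonds, inv_inst, invp[idx],
                             r$target_inst, site[length(site) - idx + 1L])
  }

  comps <- complex_components(merged)
  prod_labels <- character(0)
  for (comp in comps) {
    if (length(comp$strands) == 1 && nrow(comp$bonds) == 0) {
      sp <- comp$strands[[1]]$name
      cur <- if (sp %in% names(sys$free)) sys$free[[sp]] else 0L
      sys$free[[sp]] <- cur + 1L
      prod_labels <- c(prod_labels, paste0("free:", sp))
    } else {
      comp$count <- 1L
      sys <- sys_merge_complex(sys, comp)
      prod_labels <- c(prod_labels, paste(sort(vapply(
        comp$strands, `[[`, character(1), "name")), collapse = "+"))
    }
  }
  sys_trace(sys, "invade",
            c(r$invader_species, paste0("complex:", r$target_inst)),
            prod_labels, pairing_gain = r$pairing_gain,
            note = sprintf("site %s on %s, toehold %d nt, %d bp formed",
                           paste(range(r$site), collapse = "-"),
                           r$target_inst, r$toehold_nt, r$formed_nt))
}

# Re-pair co-localized original partners: within a non-inert complex, any
# two unpaired complementary domain instances re-form their duplex. Runs
# only when no displacement applies (lowest priority); this is the
# re-closure step after an erase strand strips an opener off an edge.
reclose_step <- function(sys) {
  for (ci in seq_along(sys$complexes)) {
    cx <- sys$complexes[[ci]]
    if (cx$inert) next
    pm <- paired_map(cx)
    insts <- sort(names(cx$strands))
    for (i1 in seq_along(insts)) {
      s1 <- insts[i1]
      d1 <- cx$strands[[s1]]$domains
      for (p1 in seq_along(d1)) {
        if (pm[[s1]][p1]) next
        for (i2 in seq_along(insts)) {
          if (i2 <= i1) next
          s2 <- insts[i2]
          d2 <- cx$strands[[s2]]$domains
          for (p2 in seq_along(d2)) {
            if (pm[[s2]][p2]) next
            if (dom_partner(d1[p1]) == d2[p2]) {
              cx$bonds <- add_bond(cx$bonds, s1, p1, s2, p2)
              pm[[s1]][p1] <- TRUE
              pm[[s2]][p2] <- TRUE
              sys$complexes[[ci]] <- cx
              sys <- sys_trace(sys, "reclose",
                               c(paste0(s1, ":", p1), paste0(s2, ":", p2)),
                               cx$label,
                               pairing_gain = dom_len(sys$lib, d1[p1]))
              return(list(sys = sys, changed = TRUE))
            }
          }
        }
      }
    }
  }
  list(sys = sys, changed = FALSE)
}

#' Run a reaction system to its fixed point
#'
#' Repeatedly applies the rule phases in priority order - fold hairpins,
#' resolve solution-phase sequestration, apply the highest-priority
#' invasion, re-pair vacated original partners - until no reaction
#' applies. Newly uncaged segments (e.g. the released C2 block of an
#' activated hairpin) become eligible invaders in later iterations.
#'
#' @param sys A reaction system.
#' @param choose Optional function selecting which enumerated invasion to
#'   apply at each step (`function(reactions) -> index`); the default takes
#'   the highest-priority one. Used to probe order-independence.
#' @return The system at its fixed point.
#' @export
react_to_fixed_point <- function(sys, choose = NULL) {
  for (iter in seq_len(sys$params$max_iter)) {
    n_trace <- length(sys$trace)
    sys <- fold_hairpins(sys)
    sys <- resolve_solution_hybridization(sys)
    if (length(sys$trace) > n_trace) next
    inv <- enumerate_invasions(sys)
    if (length(inv) > 0) {
      idx <- if (is.null(choose)) 1L else choose(inv)
      sys <- apply_invasion(sys, inv[[idx]])
      next
    }
    rc <- reclose_step(sys)
    sys <- rc$sys
    if (rc$changed) next
    return(sys)
  }
  stop("engine error: no fixed point within ", sys$params$max_iter,
       " iterations (", length(sys$trace), " reactions applied)",
       call. = FALSE)
}

#' Erase an opener strand off the prism and re-close the edge
#'
#' Introduces the eraser (the full complement of an erasable opener,
#' carrying an external 10-nt toehold), which captures the opener into a
#' waste duplex; the vacated edge then re-forms its original 10-bp bond
#' and the prism reverts toward the closed state. If no matching bound
#' opener is present the call is a no-op recorded as a warning in the
#' trace.
#'
#' @param sys A reaction system.
#' @param erase_strand Eraser species name (`"Es1"` or `"Es2"`).
#' @return The updated system at its fixed point.
#' @export
erase <- function(sys, erase_strand) {
  if (!grepl("^Es", erase_strand)) {
    stop("erase_strand must be an eraser species (Es1/Es2)", call. = FALSE)
  }
  is_name <- sub("^Es", "Is", erase_strand)
  bound <- any(vapply(sys$complexes, function(cx) {
    !cx$inert && is_name %in% vapply(cx$strands, `[[`, character(1), "name")
  }, logical(1)))
  if (!bound) {
    return(sys_trace(sys, "erase", erase_strand, character(0),
                     note = paste0("warning: no bound ", is_name,
                                   "; erase is a no-op")))
  }
  sys <- add_inputs(sys, erase_strand)
  react_to_fixed_point(sys)
}

#' @export
print.reaction_system <- function(x, ...) {
  cat(sprintf("<reaction_system> %d complex species, %d free species, %d reactions in trace\n",
              length(x$complexes), sum(x$free > 0), length(x$trace)))
  for (cx in x$complexes) print(cx)
  fr <- x$free[x$free > 0]
  if (length(fr) > 0) {
    cat("free:", paste(names(fr), fr, sep = " x", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reaction trace of a system as a tibble
#'
#' @param x A reaction system.
#' @param ... Unused.
#' @return A tibble with one row per applied reaction: rule, reactants,
#'   products, pairing gain in nt.
#' @export
tidy.reaction_system <- function(x, ...) {
  tibble::tibble(
    step = seq_along(x$trace),
    rule = vapply(x$trace, `[[`, character(1), "rule"),
    reactants = vapply(x$trace, function(r)
      paste(r$reactants, collapse = " + "), character(1)),
    products = vapply(x$trace, function(r)
      paste(r$products, collapse = " + "), character(1)),
    pairing_gain = vapply(x$trace, `[[`, integer(1), "pairing_gain")
  )
}

#' Export a reaction trace as JSON lines
#'
#' One JSON record per applied reaction (rule, reactants, products,
#' pairing gain, note), for audit.
#'
#' @param sys A reaction system.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_jsonl <- function(sys, path) {
  lines <- vapply(sys$trace, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Explore all reaction orderings of a system
#'
#' Brute-force interleaving: depth-first search over every order in which
#' the applicable same-priority (equal pairing-gain) invasions could be
#' applied, with memoization on canonical system states. Used to verify
#' confluence: on all gate instances the final prism state is invariant
#' under the order of same-priority reaction application, so the engine's
#' lexicographic tie-break is immaterial.
#'
#' @param sys A reaction system.
#' @param max_states Safety cap on visited states.
#' @return Character vector of distinct final prism-state labels.
#' @export
explore_orders <- function(sys, max_states = 2000) {
  seen <- new.env(parent = emptyenv())
  finals <- new.env(parent = emptyenv())
  visited <- 0L
  recurse <- function(s) {
    key <- system_key(s)
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    visited <<- visited + 1L
    if (visited > max_states) stop("state cap exceeded", call. = FALSE)
    s <- fold_hairpins(s)
    s <- resolve_solution_hybridization(s)
    inv <- enumerate_invasions(s)
    if (length(inv) == 0) {
      rc <- reclose_step(s)
      while (rc$changed) rc <- reclose_step(rc$sys)
      finals[[prism_state(rc$sys)$label]] <- TRUE
      return(invisible(NULL))
    }
    gains <- vapply(inv, `[[`, integer(1), "pairing_gain")
    for (i in which(gains == max(gains))) {
      recurse(apply_invasion(s, inv[[i]]))
    }
  }
  recurse(sys)
  sort(ls(finals))
}
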