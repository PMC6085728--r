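test_that("hairpin folding cages the embedded opener", {
  sys <- fold_hairpins(mk_sys("C2H"))
  expect_equal(unname(sys$free[["C2H"]]), 0)
  folded <- Filter(function(cx) grepl("C2H", cx$label), sys$complexes)
  expect_equal(length(folded), 1)
  # the caged C2 block cannot open edge 2
  done <- react_to_fixed_point(sys)
  expect_equal(prism_state(done)$label, "closed")
})

test_that("folding is a no-op without hairpin declarations", {
  sys <- mk_sys("C1")
  sys2 <- fold_hairpins(sys)
  expect_equal(length(sys2$trace), 0)
  expect_identical(sys2$free, sys$free)
  empty <- fold_hairpins(mk_sys())
  expect_equal(length(empty$trace), 0)
})

test_that("solution sequestration annihilates complementary inputs into inert waste", {
  sys <- resolve_solution_hybridization(mk_sys(c("C1", "C1p")))
  expect_equal(unname(sys$free[["C1"]]), 0)
  expect_equal(unname(sys$free[["C1p"]]), 0)
  waste <- Filter(function(cx) cx$inert, sys$complexes)
  expect_equal(length(waste), 1)
  expect_equal(sum(vapply(seq_len(nrow(waste[[1]]$bonds)), function(k)
    prismlogic:::dom_len(sys$lib,
      waste[[1]]$strands[[waste[[1]]$bonds$s1[k]]]$domains[
        waste[[1]]$bonds$p1[k]]), integer(1))), 16)  # full 16-bp duplex
  # nothing is left to invade: the prism stays closed
  expect_equal(prism_state(react_to_fixed_point(sys))$label, "closed")
})

test_that("the mutually complementary XOR inputs sequester each other", {
  sys <- resolve_solution_hybridization(mk_sys(c("XOR1", "XOR2")))
  expect_equal(unname(sys$free[["XOR1"]]), 0)
  expect_equal(unname(sys$free[["XOR2"]]), 0)
  expect_true(any(vapply(sys$complexes, function(cx) cx$inert, logical(1))))
})

test_that("non-complementary strands do not pair in solution", {
  sys <- resolve_solution_hybridization(mk_sys(c("C1", "C2p")))
  expect_equal(unname(sys$free[["C1"]]), sys$params$input_excess)
  expect_equal(unname(sys$free[["C2p"]]), sys$params$input_excess)
  expect_equal(length(Filter(function(cx) cx$inert, sys$complexes)), 0)
})

test_that("invasion enumeration finds edge openings and hairpin activations only where a toehold exists", {
  inv <- enumerate_invasions(mk_sys("C2"))
  expect_gte(length(inv), 1)
  expect_equal(inv[[1]]$invader_species, "C2")
  expect_equal(inv[[1]]$target_inst, "B2")
  # an inhibitor has no exposed complement on the closed prism
  expect_equal(length(enumerate_invasions(mk_sys("C1p"))), 0)
  # the activator opens the folded hairpin through the 2-nt toehold
  sysh <- fold_hairpins(mk_sys(c("C2H", "AND2")))
  invh <- enumerate_invasions(sysh)
  targets <- vapply(invh, `[[`, character(1), "target_inst")
  expect_true("C2H" %in% targets)
  hp <- invh[[which(targets == "C2H")[1]]]
  expect_equal(hp$toehold_nt, 2)
})

test_that("reactions run to a fixed point with conserved strands", {
  sys0 <- mk_sys(c("C1", "C2", "C3"))
  before <- prismlogic:::strand_census(sys0)
  sys <- react_to_fixed_point(sys0)
  expect_identical(prismlogic:::strand_census(sys), before)
  st <- prism_state(sys)
  expect_false(st$connected)
  # empty system: nothing happens
  sysE <- react_to_fixed_point(mk_sys())
  expect_equal(length(sysE$trace), 0)
  expect_equal(prism_state(sysE)$label, "closed")
})

test_that("hairpin activation unfastens edge 2 and gives a high signal", {
  sys <- react_to_fixed_point(mk_sys(c("C2H", "AND2")))
  st <- prism_state(sys)
  expect_true(2 %in% st$opened_edges)
  expect_gt(nfi(st), 0.6)
})

test_that("the eraser strips the opener and the edge re-closes", {
  sys <- react_to_fixed_point(mk_sys("Is2"))
  expect_equal(prism_state(sys)$label, "mono-SD(C2)")
  sys <- erase(sys, "Es2")
  expect_equal(prism_state(sys)$label, "closed")
  # waste duplex Wd contains the stripped opener
  waste_species <- unlist(lapply(sys$complexes, function(cx)
    if (!any(c("LA", "LB") %in% vapply(cx$strands, `[[`, character(1),
                                       "name")))
      vapply(cx$strands, `[[`, character(1), "name")))
  expect_true("Is2" %in% waste_species)
  expect_true("Es2" %in% waste_species)
})

test_that("erasing with nothing bound is a warned no-op", {
  sys <- mk_sys()
  sys2 <- erase(sys, "Es2")
  expect_equal(prism_state(sys2)$label, "closed")
  last <- sys2$trace[[length(sys2$trace)]]
  expect_match(last$note, "no-op")
  expect_error(erase(sys, "C1"), "eraser")
})

test_that("every gate run conserves the strand multiset and terminates", {
  gates <- test_gates()
  for (g in gates) {
    grid <- expand.grid(rep(list(0:(g$valence - 1)), g$arity))
    for (k in seq_len(nrow(grid))) {
      sys0 <- mk_sys(gate_species(g, unlist(grid[k, ])))
      before <- prismlogic:::strand_census(sys0)
      sys <- react_to_fixed_point(sys0)
      expect_identical(prismlogic:::strand_census(sys), before)
      expect_lte(length(sys$trace), sys$params$max_iter)
    }
  }
})

test_that("the endpoint is confluent on every gate instance", {
  gates <- test_gates()
  for (g in gates) {
    grid <- expand.grid(rep(list(0:(g$valence - 1)), g$arity))
    for (k in seq_len(nrow(grid))) {
      vals <- unlist(grid[k, ])
      finals <- explore_orders(mk_sys(gate_species(g, vals)))
      expect_length(finals, 1)
      ref <- prism_state(react_to_fixed_point(mk_sys(gate_species(g, vals))))
      expect_equal(finals, ref$label)
    }
  }
})

test_that("adding an input's full complement never opens more edges", {
  cases <- list(
    list(base = "C1", comp = "C1p"),
    list(base = "C2", comp = "C2p"),
    list(base = c("C1", "C2"), comp = "C2p"),
    list(base = c("C1", "C2", "C3"), comp = "C1p"),
    list(base = "Is1", comp = "Es1")
  )
  for (cs in cases) {
    open_base <- prism_state(react_to_fixed_point(mk_sys(cs$base)))$opened_edges
    open_with <- prism_state(react_to_fixed_point(
      mk_sys(c(cs$base, cs$comp))))$opened_edges
    expect_true(all(open_with %in% open_base))
  }
})

test_that("the trace records rule, reactants, products and pairing gain", {
  sys <- react_to_fixed_point(mk_sys(c("C1", "C1p", "C2")))
  tr <- tidy(sys)
  expect_true(all(c("rule", "reactants", "products", "pairing_gain")
                  %in% names(tr)))
  expect_setequal(unique(tr$rule), c("sequester", "invade"))
  expect_true(all(tr$pairing_gain > 0))
})
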