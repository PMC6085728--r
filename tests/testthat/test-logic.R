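test_that("the built-in library provides the seven gates", {
  gates <- test_gates()
  expect_setequal(names(gates),
                  c("OR", "AND", "XOR", "INHIBIT", "INHIBIT-OR",
                    "INHIBIT-OR-2", "ternary-INHIBIT"))
  expect_equal(gates$OR$arity, 2)
  expect_equal(gates$`ternary-INHIBIT`$valence, 3)
  expect_equal(gates$`ternary-INHIBIT`$inputs[[2]][[3]], c("C2p", "C1p"))
  expect_equal(gates$AND$inputs[[1]][[2]], "C2H")
  # value 0 always encodes the empty multiset
  for (g in gates) {
    for (inp in g$inputs) expect_length(inp[[1]], 0)
  }
})

test_that("gate specifications are validated", {
  lib <- test_lib()
  expect_error(gate_spec("bad", list(list("C1", "C2")), lib = lib),
               "value 0")
  expect_error(gate_spec("bad", list(list(character(0), "NOPE")), lib = lib),
               "unknown strands")
  expect_error(gate_spec("bad", list(list(character(0))), lib = lib),
               "values")
})

test_that("binary truth tables equal their Boolean specifications", {
  gates <- test_gates()
  tts <- lapply(gates[c("OR", "AND", "XOR", "INHIBIT")], truth_table,
                lib = test_lib())
  expect_equal(tts$OR$output, c(0L, 1L, 1L, 1L))
  expect_equal(tts$AND$output, c(0L, 0L, 0L, 1L))
  expect_equal(tts$XOR$output, c(0L, 1L, 1L, 0L))
  expect_equal(tts$INHIBIT$output, c(0L, 0L, 1L, 0L))
  # against the Boolean forms over the same lexicographic rows
  rows <- expand.grid(in2 = 0:1, in1 = 0:1)[, 2:1]
  expect_equal(tts$OR$output, as.integer(rows$in1 | rows$in2))
  expect_equal(tts$AND$output, as.integer(rows$in1 & rows$in2))
  expect_equal(tts$XOR$output, as.integer(xor(rows$in1, rows$in2)))
  expect_equal(tts$INHIBIT$output, as.integer(rows$in1 & !rows$in2))
  # XOR (1/1): the prism stays closed because the inputs pair with each other
  expect_equal(tts$XOR$state[4], "closed")
  # intermediate structures match the narrative
  expect_equal(tts$OR$state, c("closed", "mono-SD(C2)", "mono-SD(C1)",
                               "di-SD(C1/C2)"))
})

test_that("three-input INHIBIT-OR tables are false exactly where inhibition wins", {
  gates <- test_gates()
  tt <- truth_table(gates$`INHIBIT-OR`, lib = test_lib())
  false_rows <- tt[tt$output == 0, c("in1", "in2", "in3")]
  expect_equal(nrow(tt), 8)
  expect_setequal(
    apply(false_rows, 1, paste, collapse = "/"),
    c("0/0/0", "0/1/0", "1/1/0"))
  # (C1 AND NOT C1p) OR C2
  expect_equal(tt$output, as.integer((tt$in1 & !tt$in2) | tt$in3))

  tt2 <- truth_table(gates$`INHIBIT-OR-2`, lib = test_lib())
  expect_equal(tt2$output, as.integer(tt2$in1 | (tt2$in2 & !tt2$in3)))
})

test_that("the ternary INHIBIT table matches the nine printed rows", {
  tt <- truth_table(test_gates()$`ternary-INHIBIT`, lib = test_lib())
  expect_equal(nrow(tt), 9)
  got <- stats::setNames(tt$output, paste(tt$in1, tt$in2, sep = "/"))
  expect_equal(got[c("0/0", "0/1", "0/2", "1/2", "2/2")],
               c("0/0" = 0L, "0/1" = 0L, "0/2" = 0L, "1/2" = 0L,
                 "2/2" = 0L))
  expect_equal(got[c("1/0", "1/1", "2/1")],
               c("1/0" = 1L, "1/1" = 1L, "2/1" = 1L))
  expect_equal(got[["2/0"]], 2L)
  # outputs are decoded from structure identity
  expect_equal(tt$state[tt$in1 == 2 & tt$in2 == 0], "di-SD(C1/C2)")
  expect_equal(tt$state[tt$in1 == 1 & tt$in2 == 1], "mono-SD(C1)")
})

test_that("an unmapped final structure raises a decode error", {
  lib <- test_lib()
  g <- gate_spec("bad-ternary", list(list(character(0), "C3", "C3")),
                 valence = 3, decoder = "structure", lib = lib)
  expect_error(evaluate_gate(g, 1, lib = lib), "decode error")
})

test_that("input vectors are validated", {
  gates <- test_gates()
  expect_error(evaluate_gate(gates$OR, c(0, 1, 1)), "input error")
  expect_error(evaluate_gate(gates$OR, c(0, 2)), "input error")
  expect_error(evaluate_gate(gates$`ternary-INHIBIT`, c(3, 0)), "input error")
})

test_that("BCD encoding is standard 8421", {
  expect_equal(unname(encode_bcd(0)), c(0, 0, 0, 0))
  expect_equal(unname(encode_bcd(7)), c(0, 1, 1, 1))
  expect_equal(unname(encode_bcd(9)), c(1, 0, 0, 1))
  expect_equal(vapply(0:9, function(d) sum(encode_bcd(d) * c(8, 4, 2, 1)),
                      numeric(1)), as.numeric(0:9))
  expect_error(encode_bcd(12), "input error")
  expect_error(encode_bcd(-1), "input error")
})

test_that("the even/odd identifier outputs the digit parity for 0-9", {
  pt <- parity_table(lib = test_lib())
  expect_equal(pt$output, pt$digit %% 2)
  expect_true(all(pt$nfi[pt$digit %% 2 == 1] > 0.6))
  expect_true(all(pt$nfi[pt$digit %% 2 == 0] < 0.6))
  # structures match the mechanism: 4 opens only edge 3; 0 adds nothing
  expect_equal(pt$state[pt$digit == 4], "mono-SD(C3)")
  expect_equal(pt$state[pt$digit == 0], "closed")
  ev7 <- classify_parity(7, lib = test_lib())
  expect_equal(ev7$output, 1L)
  expect_gt(ev7$nfi, 0.6)
})

test_that("open/erase cycling alternates across the threshold and ends closed", {
  for (edge in 1:2) {
    cyc <- run_cycle(edge, 3, lib = test_lib())
    expect_equal(nrow(cyc), 6)
    expect_true(all(cyc$nfi[cyc$action == "open"] > 0.6))
    expect_true(all(cyc$nfi[cyc$action == "erase"] < 0.6))
    expect_equal(cyc$state[6], "closed")
  }
  one <- run_cycle(2, 1, lib = test_lib())
  expect_equal(one$action, c("open", "erase"))
  expect_true(one$nfi[1] > 0.6 && one$nfi[2] < 0.6)
  expect_error(run_cycle(1, 0), "input error")
  expect_error(run_cycle(3, 1), "input error")
})

test_that("gate outputs do not depend on the sequence fixture", {
  # logic is decided at domain level: two different nucleotide assignments
  # share the identical domain structure, so every evaluation is unchanged
  expect_identical(tidy(test_lib()), tidy(test_lib()))
  s1 <- test_seqs(1); s2 <- test_seqs(2)
  expect_false(identical(s1$strand_seqs, s2$strand_seqs))
  tt_a <- truth_table(test_gates()$OR, lib = test_lib())
  tt_b <- truth_table(builtin_gates(test_lib())$OR, lib = test_lib())
  expect_equal(tt_a$output, tt_b$output)
})

test_that("tidiers and plots summarize results", {
  tt <- truth_table(test_gates()$OR, lib = test_lib())
  g <- glance(tt)
  expect_equal(g$n_rows, 4)
  expect_equal(g$n_true, 3)
  ev <- evaluate_gate(test_gates()$OR, c(0, 1), lib = test_lib())
  td <- tidy(ev)
  expect_equal(td$output, 1L)
  expect_equal(td$state, "mono-SD(C2)")
  expect_s3_class(autoplot(tt), "ggplot")
  expect_s3_class(autoplot(run_cycle(1, 1, lib = test_lib())), "ggplot")
  expect_s3_class(autoplot(parity_table(0:1, lib = test_lib())), "ggplot")
  expect_s3_class(plot_prism_geometry(), "ggplot")
})
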