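test_that("architecture invariants are enforced", {
  spec <- architecture_spec()
  expect_equal(spec$b_tail, spec$a_tail + spec$toehold)
  expect_error(architecture_spec(b_tail = 15), "b_tail")
  expect_error(architecture_spec(a_tail = -1), "positive")
  expect_error(architecture_spec(face_bp = 0), "positive")
  expect_error(architecture_spec(xor_ext3 = 10, xor_ext5 = 10), "xor_ext3")
})

test_that("complementation is an involution that preserves length", {
  lib <- test_lib()
  for (d in names(lib$domains)) {
    dc <- domain_complement(lib, d)
    expect_equal(domain_complement(lib, dc), d)
    expect_equal(prismlogic:::dom_len(lib, dc), prismlogic:::dom_len(lib, d))
  }
  expect_equal(domain_complement(lib, "t1"), "t1*")
  expect_error(domain_complement(lib, "nope"), "unknown domain")
})

test_that("nucleotide-level complementation follows the Watson-Crick rule", {
  expect_equal(dna_revcomp("ACGTAC"), "GTACGT")
  expect_equal(dna_revcomp(dna_revcomp("GATTACA")), "GATTACA")
  expect_error(dna_revcomp("ACGU"), "alphabet")
})

test_that("canonical strands have the printed lengths", {
  lib <- test_lib()
  # openers are exactly the 16-nt complements of the full B tails
  expect_equal(strand_length(lib, "C1"), 16)
  expect_equal(strand_length(lib, "C2"), 16)
  expect_equal(strand_length(lib, "C3"), 16)
  # XOR inputs: 10 nt (5') + 16 nt core + 14 nt (3')
  expect_equal(strand_length(lib, "XOR1"), 40)
  expect_equal(strand_length(lib, "XOR2"), 40)
  # AND activator: C3 plus 2 nt
  expect_equal(strand_length(lib, "AND2"), 18)
  # erasable openers: opener plus the external 10-nt toehold
  expect_equal(strand_length(lib, "Is1"), 26)
  expect_equal(strand_length(lib, "Es1"), 26)
  # A tails 10 nt, B tails 16 nt beyond the 21-nt face-side domain
  for (i in 1:3) {
    expect_equal(strand_length(lib, paste0("A", i)) - 21, 10)
    expect_equal(strand_length(lib, paste0("B", i)) - 21, 16)
  }
})

test_that("hairpin declarations are equal-length complementary segments", {
  lib <- test_lib()
  h <- lib$strands[["C2H"]]
  expect_false(is.null(h$hairpin))
  for (p in h$hairpin) {
    d1 <- h$domains[p[1]]
    d2 <- h$domains[p[2]]
    expect_equal(prismlogic:::dom_partner(d1), d2)
    expect_equal(prismlogic:::dom_len(lib, d1), prismlogic:::dom_len(lib, d2))
  }
})

test_that("complementary stretch scan matches trivial cases and the brute-force oracle", {
  expect_equal(max_complementary_stretch("AAAA", "TTTT"), 4)
  expect_equal(max_complementary_stretch("AAAA", "AAAA"), 0)
  expect_equal(max_complementary_stretch("ACGT", "ACGT"), 4)  # palindrome
  expect_error(max_complementary_stretch("ACGU", "ACGT"), "alphabet")
  withr::with_seed(7, {
    for (rep in 1:20) {
      s1 <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
      s2 <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
      expect_equal(max_complementary_stretch(s1, s2), brute_stretch(s1, s2))
    }
  })
})

test_that("sequence generation is deterministic and honours the declared lengths", {
  lib <- test_lib()
  seqs <- test_seqs(1)
  for (nm in names(lib$strands)) {
    expect_equal(nchar(seqs$strand_seqs[[nm]]), strand_length(lib, nm))
  }
  again <- generate_sequences(lib, seed = 1)
  expect_identical(seqs$strand_seqs, again$strand_seqs)
  other <- test_seqs(2)
  expect_false(identical(seqs$strand_seqs, other$strand_seqs))
})

test_that("generated sequences satisfy design hygiene", {
  lib <- test_lib()
  seqs <- test_seqs(1)
  for (d in names(lib$domains)) {
    s <- seqs$domain_seqs[[d]]
    chars <- strsplit(s, "")[[1]]
    expect_lte(max(rle(chars)$lengths), 4)
    if (nchar(s) >= 5) {
      frac <- mean(chars %in% c("G", "C"))
      expect_gte(frac, 0.40)
      expect_lte(frac, 0.60)
    }
  }
})

test_that("the orthogonality audit passes and intended duplexes are perfect", {
  lib <- test_lib()
  for (seed in c(1, 2)) {
    seqs <- test_seqs(seed)
    audit <- orthogonality_audit(lib, seqs)
    expect_true(all(audit$ok))
    # intended duplex: C1 is perfectly complementary to the full B1 tail
    b1_tail <- substr(seqs$strand_seqs[["B1"]], 22, 37)
    expect_equal(max_complementary_stretch(seqs$strand_seqs[["C1"]], b1_tail),
                 16)
    # non-partner pair from the audit's derived example
    b2_tail <- substr(seqs$strand_seqs[["B2"]], 22, 37)
    expect_lte(max_complementary_stretch(seqs$strand_seqs[["C1"]], b2_tail),
               5)
  }
})

test_that("unsatisfiable constraints raise a generation error", {
  expect_error(generate_sequences(test_lib(), seed = 1, max_stretch = 0,
                                  max_tries = 3),
               "generation failed")
  expect_error(generate_sequences(test_lib()), "seed")
})

test_that("strand structure is seed-independent", {
  libA <- build_canonical_strands(architecture_spec())
  libB <- build_canonical_strands(architecture_spec())
  expect_identical(tidy(libA), tidy(libB))
  expect_identical(tidy(libA), tidy(test_lib()))
})
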