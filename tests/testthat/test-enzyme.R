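test_that("the three promiscuity classes match their textbook examples", {
  parts <- b_antigen_parts()
  # root-sensitive fucosyltransferase: exactly one site on the precursor
  expect_equal(nrow(match_sites(parts$fut2_rs, parts$input)), 1L)
  # ... and none when the same Gal is not on a GlcNAc root
  ab <- parts$alphabet
  wrong_root <- parse_oligomer("Gal(3-1)Gal", ab)
  expect_equal(nrow(match_sites(parts$fut2_rs, wrong_root)), 0L)

  # branch-sensitive GTB needs the fucose branch
  expect_equal(nrow(match_sites(parts$gtb_bs, parts$h_antigen)), 1L)
  expect_equal(nrow(match_sites(parts$gtb_bs, parts$input)), 0L)

  # context-free enzymes act on every eligible monomer
  cf <- enzyme_rule("cf", donor_type = "Fuc", acceptor_type = "Gal",
                    acceptor_carbon = 2, class = "cf", alphabet = ab)
  chain3 <- parse_oligomer("Gal(3-1)Gal(3-1)Gal(3-1)GlcNAc", ab)
  expect_equal(nrow(match_sites(cf, chain3)), 3L)
})

test_that("match_sites returns only free sites, in canonical DFS order", {
  parts <- b_antigen_parts()
  cf <- enzyme_rule("cf", donor_type = "Gal", acceptor_type = "Gal",
                    acceptor_carbon = 3, class = "cf", alphabet = parts$alphabet)
  m <- match_sites(cf, parts$b_antigen)
  # the mid Gal's carbon 3 is occupied by the top Gal; only the top Gal matches
  expect_equal(nrow(m), 1L)
  expect_equal(m$path[[1]], c(3L, 3L))
})

test_that("apply_enzyme reproduces the B-antigen assembly steps", {
  parts <- b_antigen_parts()
  h <- apply_enzyme(parts$fut2_rs, parts$input,
                    match_sites(parts$fut2_rs, parts$input)$node[1])
  expect_true(oligomer_equal(h, parts$h_antigen))
  b <- apply_enzyme(parts$gtb_bs, h, match_sites(parts$gtb_bs, h)$node[1])
  expect_true(oligomer_equal(b, parts$b_antigen))
  expect_error(apply_enzyme(parts$gtb_bs, parts$input, 2L), "does not match")
})

test_that("forbidden branches and wildcards constrain matching", {
  ab <- blood_alphabet()
  lacking <- enzyme_rule("noFuc", donor_type = "Gal", acceptor_type = "Gal",
                         acceptor_carbon = 3, class = "bs",
                         forbidden_branches = "*2", alphabet = ab)
  bare <- parse_oligomer("Gal(3-1)GlcNAc", ab)
  fuc <- parse_oligomer("[Fuc(2-1)]Gal(3-1)GlcNAc", ab)
  expect_equal(nrow(match_sites(lacking, bare)), 1L)
  expect_equal(nrow(match_sites(lacking, fuc)), 0L)

  exact_forbid <- enzyme_rule("notFucExact", donor_type = "Gal",
                              acceptor_type = "Gal", acceptor_carbon = 3,
                              class = "bs", forbidden_branches = "Fuc(2-1)",
                              alphabet = ab)
  expect_equal(nrow(match_sites(exact_forbid, bare)), 1L)
  expect_equal(nrow(match_sites(exact_forbid, fuc)), 0L)
})

test_that("enzyme_rule validates its constraint fields", {
  ab <- blood_alphabet()
  expect_error(enzyme_rule("x", donor_type = "Fuc", acceptor_type = "Gal",
                           acceptor_carbon = 9, class = "cf", alphabet = ab),
               "not an acceptor carbon")
  expect_error(enzyme_rule("x", donor_type = "Fuc", acceptor_type = "Gal",
                           acceptor_carbon = 2, class = "cf",
                           required_branches = "Fuc(3-1)", alphabet = ab),
               "only meaningful")
  expect_error(enzyme_rule("x", donor_type = "Fuc", acceptor_type = "Gal",
                           acceptor_carbon = 2, class = "bs",
                           required_branches = "Fuc(3-1)",
                           forbidden_branches = "*3", alphabet = ab),
               "disjoint")
  expect_error(is_trigger_disabled(
    enzyme_rule("x", donor_type = "Fuc", acceptor_type = "Gal",
                acceptor_carbon = 2, class = "cf", alphabet = ab),
    compartment(list(enzyme_rule("y", donor_type = "Fuc",
                                 acceptor_type = "Gal", acceptor_carbon = 2,
                                 class = "cf", alphabet = ab)))),
    "branch-sensitive")
})

test_that("make_ideal_enzyme realizes a step with class-dependent promiscuity", {
  parts <- b_antigen_parts()
  h <- parts$h_antigen
  # root-sensitive construction pins exactly one site
  e_rs <- make_ideal_enzyme("rs", h, node = 2L, carbon = 3, donor = "Gal")
  expect_equal(nrow(match_sites(e_rs, h)), 1L)
  # branch-sensitive construction reproduces GTB behavior
  e_bs <- make_ideal_enzyme("bs", h, node = 2L, carbon = 3, donor = "Gal")
  expect_equal(nrow(match_sites(e_bs, h)), 1L)
  expect_equal(nrow(match_sites(e_bs, parts$input)), 0L)
  b <- apply_enzyme(e_bs, h, 2L)
  expect_true(oligomer_equal(b, parts$b_antigen))
  # context-free construction sees every eligible monomer
  ab <- parts$alphabet
  two_gal <- parse_oligomer("Gal(3-1)Gal(3-1)GlcNAc", ab)
  e_cf <- make_ideal_enzyme("cf", two_gal, node = 3L, carbon = 2, donor = "Fuc")
  expect_equal(nrow(match_sites(e_cf, two_gal)), 2L)
  # forbid_absent variant excludes already-branched acceptors elsewhere
  e_bs2 <- make_ideal_enzyme("bs", parts$input, node = 2L, carbon = 2,
                             donor = "Fuc", forbid_absent = TRUE)
  expect_gt(length(e_bs2$forbidden_branches), 0L)
})

test_that("promiscuity classes are nested: rs sites within bs within cf", {
  ab <- default_alphabet()
  set.seed(21)
  for (i in 1:40) {
    o <- generate_random_oligomer(ab, 7)
    fs <- free_sites(o)
    if (nrow(fs) == 0L) next
    s <- fs[sample.int(nrow(fs), 1L), ]
    donor <- sample(names(ab), 1)
    ers <- make_ideal_enzyme("rs", o, node = s$node, carbon = s$carbon,
                             donor = donor)
    ebs <- make_ideal_enzyme("bs", o, node = s$node, carbon = s$carbon,
                             donor = donor)
    ecf <- make_ideal_enzyme("cf", o, node = s$node, carbon = s$carbon,
                             donor = donor)
    n_rs <- match_sites(ers, o)$node
    n_bs <- match_sites(ebs, o)$node
    n_cf <- match_sites(ecf, o)$node
    expect_true(all(n_rs %in% n_bs))
    expect_true(all(n_bs %in% n_cf))
    expect_true(s$node %in% n_rs) # the constructed enzyme matches its own step
  }
})

test_that("enzyme libraries round-trip through YAML", {
  parts <- b_antigen_parts()
  lib <- list(parts$fut2_cf, parts$gtb_bs, parts$fut2_rs)
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_enzyme_library(lib, tf)
  back <- read_enzyme_library(tf, parts$alphabet)
  expect_identical(
    vapply(back, glycompart:::enzyme_key, character(1)),
    vapply(lib, glycompart:::enzyme_key, character(1))
  )
})
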