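test_that("reaction networks enumerate growth orders and flag runaway caps", {
  parts <- b_antigen_parts()
  # single enzyme, single matching site: two states, one terminal
  net <- build_reaction_network(compartment(parts$fut2_cf), parts$input, 8)
  expect_length(net$states, 2L)
  expect_length(net$terminal, 1L)
  expect_false(net$truncated)

  # context-free self-extension runs into the cap along a chain
  ab <- parts$alphabet
  self_gal <- enzyme_rule("selfGal", donor_type = "Gal",
                          acceptor_type = "Gal", acceptor_carbon = 3,
                          class = "cf", alphabet = ab)
  net2 <- build_reaction_network(compartment(self_gal), oligomer("Gal", ab), 6)
  expect_true(net2$truncated)
  expect_equal(max(vapply(net2$states, oligomer_size, integer(1))), 6L)

  # the promiscuous one-compartment scenario grows tandem repeats
  joint <- compartment(list(parts$fut2_cf, parts$gtb_bs))
  net3 <- build_reaction_network(joint, parts$input, 8)
  expect_true(net3$truncated)
  sizes <- vapply(net3$states, oligomer_size, integer(1))
  expect_true(any(sizes == 8L))
})

test_that("triggers deactivate branch-sensitive enzymes without their motif source", {
  parts <- b_antigen_parts()
  alone <- compartment(parts$gtb_bs)
  with_fut2 <- compartment(list(parts$fut2_cf, parts$gtb_bs))
  expect_true(is_trigger_disabled(parts$gtb_bs, alone))
  expect_false(is_trigger_disabled(parts$gtb_bs, with_fut2))
  expect_false(is_trigger_disabled(
    enzyme_rule("noreq", donor_type = "Gal", acceptor_type = "Gal",
                acceptor_carbon = 3, class = "bs",
                forbidden_branches = "*2", alphabet = parts$alphabet),
    alone))
})

test_that("linkage network records one edge per enzyme with trigger state", {
  parts <- b_antigen_parts()
  ln1 <- build_linkage_network(compartment(parts$gtb_bs))
  expect_equal(nrow(ln1), 1L)
  expect_false(ln1$active) # trigger-disabled without a fucosyltransferase
  ln2 <- build_linkage_network(compartment(list(parts$fut2_cf, parts$gtb_bs)))
  expect_true(all(ln2$active))
  expect_equal(ln2$from[ln2$enzyme == "GTBbs"], "Gal")
  expect_equal(ln2$to[ln2$enzyme == "GTBbs"], "Gal")
})

test_that("runaway detection equals loop structure of the linkage network", {
  parts <- b_antigen_parts()
  ab <- parts$alphabet
  self_gal <- enzyme_rule("selfGal", donor_type = "Gal",
                          acceptor_type = "Gal", acceptor_carbon = 3,
                          class = "cf", alphabet = ab)
  expect_length(detect_runaway(compartment(self_gal)), 1L)
  # GTB's Gal->Gal edge loops only when its trigger is synthesizable
  expect_length(detect_runaway(compartment(parts$gtb_bs)), 0L)
  joint <- compartment(list(parts$fut2_cf, parts$gtb_bs))
  expect_gte(length(detect_runaway(joint, parts$input)), 1L)
  # ideal root-sensitive enzymes never loop
  rs_lib <- generate_random_enzyme_library(default_alphabet(), 4,
                                           class_probs = c(cf = 0, bs = 0,
                                                           rs = 1),
                                           seed = 31)
  expect_length(detect_runaway(compartment(rs_lib)), 0L)

  # input-awareness: a lone self-loop enzyme whose only acceptor carbon is
  # already occupied can never start the loop
  abc <- abc_alphabet()
  selfA <- enzyme_rule("selfA", donor_type = "A", acceptor_type = "A",
                       acceptor_carbon = 3, class = "cf", alphabet = abc)
  blocked_input <- parse_oligomer("B(3-1)A", abc) # carbon 3 occupied, B inert
  expect_length(detect_runaway(compartment(selfA), blocked_input), 0L)
  expect_length(detect_runaway(compartment(selfA), oligomer("A", abc)), 1L)
})

test_that("acceptor blocks: bidirectional competition and unidirectional motifs", {
  ab <- blood_alphabet()
  e1 <- enzyme_rule("addFuc", donor_type = "Fuc", acceptor_type = "Gal",
                    acceptor_carbon = 3, class = "cf", alphabet = ab)
  e2 <- enzyme_rule("addGal", donor_type = "Gal", acceptor_type = "Gal",
                    acceptor_carbon = 3, class = "cf", alphabet = ab)
  bl <- detect_acceptor_blocks(compartment(list(e1, e2)))
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$direction, "bidirectional")

  # enzyme requiring an unbranched acceptor is blocked by any brancher
  lacking <- enzyme_rule("noBranch", donor_type = "Gal",
                         acceptor_type = "Gal", acceptor_carbon = 3,
                         class = "bs", forbidden_branches = "*2",
                         alphabet = ab)
  brancher <- enzyme_rule("addFuc2", donor_type = "Fuc",
                          acceptor_type = "Gal", acceptor_carbon = 2,
                          class = "cf", alphabet = ab)
  bl2 <- detect_acceptor_blocks(compartment(list(brancher, lacking)))
  expect_true(any(bl2$direction == "unidirectional" &
                    bl2$blocker == "addFuc2" & bl2$blocked == "noBranch"))

  # an enzyme extending a required branch destroys the ideal motif
  parts <- b_antigen_parts()
  fuc_ext <- enzyme_rule("fucExt", donor_type = "Gal", acceptor_type = "Fuc",
                         acceptor_carbon = 2, class = "cf",
                         alphabet = parts$alphabet)
  bl3 <- detect_acceptor_blocks(compartment(list(fuc_ext, parts$gtb_bs)))
  expect_true(any(bl3$direction == "unidirectional" &
                    bl3$blocked == "GTBbs"))

  expect_equal(nrow(detect_acceptor_blocks(compartment(e1))), 0L)
})

test_that("divergence requires non-reconverging forks", {
  ab <- blood_alphabet()
  # two enzymes on distinct carbons of the same monomer reconverge
  eA <- enzyme_rule("eA", donor_type = "Fuc", acceptor_type = "Gal",
                    acceptor_carbon = 2, class = "cf", alphabet = ab)
  eB <- enzyme_rule("eB", donor_type = "GlcNAc", acceptor_type = "Gal",
                    acceptor_carbon = 3, class = "cf", alphabet = ab)
  input <- parse_oligomer("Gal(3-1)GlcNAc", ab)
  net <- build_reaction_network(compartment(list(eA, eB)), input, 6)
  expect_false(net$truncated)
  expect_equal(nrow(detect_divergence(net)), 0L)

  # competing for the same carbon: one divergent fork
  eC <- enzyme_rule("eC", donor_type = "Fuc", acceptor_type = "Gal",
                    acceptor_carbon = 3, class = "cf", alphabet = ab)
  net2 <- build_reaction_network(compartment(list(eB, eC)), input, 6)
  expect_false(net2$truncated)
  expect_equal(nrow(detect_divergence(net2)), 1L)
})

test_that("every divergent fork comes with an acceptor block (small battery)", {
  abc <- abc_alphabet()
  set.seed(32)
  n_div <- 0L
  for (i in 1:200) {
    case <- draw_compartment_case(abc, n_enzymes = sample(2:3, 1))
    cap <- oligomer_size(case$input) + 8L
    probe <- build_reaction_network(case$compartment, case$input, cap,
                                    max_states = 40000,
                                    stop_on_truncation = TRUE)
    if (probe$truncated) next
    net <- build_reaction_network(case$compartment, case$input, cap,
                                  max_states = 40000)
    div <- detect_divergence(net)
    if (nrow(div) > 0L) {
      n_div <- n_div + 1L
      expect_gt(nrow(detect_acceptor_blocks(case$compartment)), 0L)
    }
  }
  expect_gt(n_div, 0L)
})

test_that("algorithmic compartments map inputs to unique outputs", {
  parts <- b_antigen_parts()
  r1 <- is_algorithmic_compartment(compartment(parts$fut2_cf), parts$input)
  expect_true(r1$algorithmic)
  expect_true(oligomer_equal(r1$output, parts$h_antigen))
  r2 <- is_algorithmic_compartment(compartment(parts$gtb_bs), parts$h_antigen)
  expect_true(r2$algorithmic)
  expect_true(oligomer_equal(r2$output, parts$b_antigen))
  r3 <- is_algorithmic_compartment(
    compartment(list(parts$fut2_cf, parts$gtb_bs)), parts$input)
  expect_false(r3$algorithmic)
  expect_null(r3$output)
})

test_that("make_algorithmic removes loops and blocks and is idempotent", {
  ab <- blood_alphabet()
  self_gal <- enzyme_rule("selfGal", donor_type = "Gal",
                          acceptor_type = "Gal", acceptor_carbon = 3,
                          class = "cf", alphabet = ab)
  indep <- enzyme_rule("indep", donor_type = "Fuc", acceptor_type = "GlcNAc",
                       acceptor_carbon = 6, class = "cf", alphabet = ab)
  fixed <- make_algorithmic(compartment(list(self_gal, indep), 2))
  expect_setequal(names(fixed$enzymes), "indep")
  expect_true(is.infinite(fixed$residence_time))
  # fixed point
  again <- make_algorithmic(fixed)
  expect_setequal(names(again$enzymes), names(fixed$enzymes))

  # arbitrary collections come out loop- and block-free, and algorithmic on
  # sub-oligomer inputs of a target they can still grow
  abc <- abc_alphabet()
  set.seed(33)
  for (i in 1:25) {
    lib <- generate_random_enzyme_library(abc, 4)
    out <- make_algorithmic(compartment(lib, 1))
    expect_length(detect_runaway(out), 0L)
    expect_equal(nrow(detect_acceptor_blocks(out)), 0L)
    if (length(out$enzymes) > 0L) {
      res <- is_algorithmic_compartment(out, oligomer(sample(names(abc), 1),
                                                      abc))
      expect_true(res$algorithmic)
    }
  }
})

test_that("classify_variability reproduces the three scenario patterns", {
  # truncated only: finite T, convergent single compartment
  mucin <- builtin_fixtures("mucin_like")
  solo <- classify_variability(list(mucin$series[[3]]),
                               parse_oligomer("GlcNAc(3-1)GalNAc",
                                              mucin$alphabet))
  expect_identical(solo$causes, "truncated")
  # full mucin series adds the upstream divergence
  full <- classify_variability(mucin$series, mucin$input)
  expect_true(all(c("divergent", "truncated") %in% full$causes))
  # horse-CG-like: runaway present
  horse <- builtin_fixtures("horse_cg_like")
  expect_true("runaway" %in% classify_variability(horse$series, horse$input)$causes)
  # human-CG-like: divergence from competing enzymes
  human <- builtin_fixtures("human_cg_like")
  expect_true("divergent" %in% classify_variability(human$series, human$input)$causes)
})

test_that("networks export to DOT and tidy tibbles", {
  parts <- b_antigen_parts()
  net <- build_reaction_network(compartment(parts$fut2_cf), parts$input, 6)
  txt <- network_to_dot(net)
  expect_match(txt, "digraph reaction_network")
  expect_match(linkage_to_dot(build_linkage_network(compartment(parts$fut2_cf))),
               "digraph linkage_network")
  expect_s3_class(tidy(net), "tbl_df")
  expect_equal(glance(net)$n_states, 2L)
})
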