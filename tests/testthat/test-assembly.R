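test_that("Shannon entropy matches closed-form anchors", {
  ab <- monomer_alphabet(c("A", "B", "C", "D"), acceptor_carbons = c(2, 3))
  quad <- lapply(c("A", "B", "C", "D"), oligomer, alphabet = ab)
  expect_equal(shannon_entropy(output_distribution(quad[1:3], c(.25, .25, .5))),
               1.5)
  expect_equal(shannon_entropy(output_distribution(quad[[1]])), 0)
  expect_equal(shannon_entropy(output_distribution(quad, rep(.25, 4))), 2)
  expect_error(shannon_entropy(c(.2, .2)), "sum to 1")
})

test_that("exact CTMC reproduces the two-state closed form P(B) = T/(1+T)", {
  ab <- monomer_alphabet(c("A", "B"), acceptor_carbons = c(2, 3))
  e <- enzyme_rule("add", donor_type = "B", acceptor_type = "A",
                   acceptor_carbon = 3, class = "cf", alphabet = ab)
  for (Tres in c(0.25, 1, 2, 7.5)) {
    d <- exact_output_distribution(compartment(e, Tres), oligomer("A", ab))
    expect_equal(d$probability[d$oligomer == "B(3-1)A"], Tres / (1 + Tres),
                 tolerance = 1e-12)
  }
})

test_that("exit limits: T->0 keeps the input, T=Inf reaches the unique terminal", {
  parts <- b_antigen_parts()
  cpt <- compartment(parts$fut2_cf, residence_time = 1e-9)
  d0 <- exact_output_distribution(cpt, parts$input)
  expect_equal(d0$probability[d0$oligomer == serialize_canonical(parts$input)],
               1, tolerance = 1e-6)
  cptInf <- compartment(parts$fut2_cf, residence_time = Inf)
  dInf <- exact_output_distribution(cptInf, parts$input)
  expect_equal(nrow(dInf), 1L)
  expect_equal(dInf$oligomer, serialize_canonical(parts$h_antigen))
  expect_equal(shannon_entropy(dInf), 0)
})

test_that("transport and maturation agree in the T->0 and T->inf limits", {
  parts <- b_antigen_parts()
  mk <- function(Tres, model) {
    exact_output_distribution(
      compartment(parts$fut2_cf, residence_time = Tres, exit_model = model),
      parts$input)
  }
  for (Tres in c(0.01, 200)) {
    dt <- mk(Tres, "transport")
    dm <- mk(Tres, "maturation")
    merged <- merge(as.data.frame(dt)[1:2], as.data.frame(dm)[1:2],
                    by = "oligomer", all = TRUE)
    merged[is.na(merged)] <- 0
    expect_lt(max(abs(merged$probability.x - merged$probability.y)), 0.02)
  }
})

test_that("probability is conserved and linear across a series", {
  mucin <- builtin_fixtures("mucin_like")
  d <- run_series(mucin$series, mucin$input)
  expect_equal(sum(d$probability), 1, tolerance = 1e-9)
  # empty series is the identity; an enzyme-free compartment changes nothing
  d0 <- run_series(list(), mucin$input)
  expect_equal(d0$oligomer, serialize_canonical(mucin$input))
  idc <- compartment(list(), residence_time = 3)
  d1 <- run_series(c(mucin$series[1:2], list(idc)), mucin$input)
  d2 <- run_series(mucin$series[1:2], mucin$input)
  expect_equal(sort(d1$oligomer), sort(d2$oligomer))
  expect_equal(d1$probability[order(d1$oligomer)],
               d2$probability[order(d2$oligomer)], tolerance = 1e-9)
})

test_that("the divergent upstream produces the 1:1:2 profile at 1.5 bits", {
  mucin <- builtin_fixtures("mucin_like")
  d <- run_series(mucin$series[1:2], mucin$input)
  expect_equal(sort(d$probability), c(0.25, 0.25, 0.5), tolerance = 1e-9)
  expect_equal(shannon_entropy(d), 1.5, tolerance = 1e-9)
})

test_that("Monte Carlo simulation is reproducible and respects concentration", {
  parts <- b_antigen_parts()
  cpt <- compartment(parts$fut2_cf, residence_time = 1)
  m1 <- simulate_compartment(cpt, parts$input, n_samples = 500, seed = 7)
  m2 <- simulate_compartment(cpt, parts$input, n_samples = 500, seed = 7)
  expect_identical(as.data.frame(m1), as.data.frame(m2))

  # a zero-concentration enzyme never fires
  dead <- enzyme_rule("dead", donor_type = "Fuc", acceptor_type = "Gal",
                      acceptor_carbon = 2, class = "cf", concentration = 0,
                      alphabet = parts$alphabet)
  m3 <- simulate_compartment(compartment(dead, residence_time = 5),
                             parts$input, n_samples = 200, seed = 8)
  expect_equal(m3$oligomer, serialize_canonical(parts$input))
  expect_equal(m3$probability, 1)
})

test_that("Monte Carlo matches the exact distribution within 3 standard errors", {
  parts <- b_antigen_parts()
  cpt <- compartment(list(parts$fut2_cf, parts$fut2_rs), residence_time = 1.2)
  n <- 20000
  ex <- exact_output_distribution(cpt, parts$input)
  mc <- simulate_compartment(cpt, parts$input, n_samples = n, seed = 9)
  for (r in seq_len(nrow(ex))) {
    p <- ex$probability[r]
    phat <- mc$probability[match(ex$oligomer[r], mc$oligomer)]
    if (is.na(phat)) phat <- 0
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(phat - p), 3 * se + 0.01)
  }
})

test_that("entropy curves have the right shapes and a flat no-enzyme baseline", {
  mucin <- builtin_fixtures("mucin_like")
  Tg <- exp(seq(log(0.05), log(50), length.out = 7))
  ec <- entropy_curve(mucin$series, mucin$input, Tg)
  expect_equal(nrow(ec), 7L)
  expect_true(all(ec$entropy_bits >= 0))
  # rises from the input entropy then falls back toward the terminal set
  expect_gt(max(ec$entropy_bits), ec$entropy_bits[1])
  expect_gt(max(ec$entropy_bits), ec$entropy_bits[7])

  # no-enzyme final stage: flat at the input entropy (1.5 bits)
  flat_series <- c(mucin$series[1:2], list(compartment(list(), 1)))
  ec2 <- entropy_curve(flat_series, mucin$input, c(0.1, 1, 10))
  expect_equal(ec2$entropy_bits, rep(1.5, 3), tolerance = 1e-9)
})

test_that("runaway with infinite residence time is rejected by the exact method", {
  ab <- blood_alphabet()
  self_gal <- enzyme_rule("selfGal", donor_type = "Gal",
                          acceptor_type = "Gal", acceptor_carbon = 3,
                          class = "cf", alphabet = ab)
  expect_error(
    exact_output_distribution(compartment(self_gal, Inf),
                              oligomer("Gal", ab), size_cap = 8),
    "runaway"
  )
  # at finite T the capped computation is flagged approximate
  expect_warning(
    d <- exact_output_distribution(compartment(self_gal, 1),
                                   oligomer("Gal", ab), size_cap = 8),
    "approximate"
  )
  expect_true(isTRUE(attr(d, "approximate")))
})

test_that("distribution objects expose tidy/glance metadata", {
  parts <- b_antigen_parts()
  d <- exact_output_distribution(compartment(parts$fut2_cf, 1), parts$input)
  td <- tidy(d)
  expect_named(td, c("oligomer", "probability", "size"))
  g <- glance(d)
  expect_equal(g$method, "exact")
  expect_equal(g$entropy_bits, shannon_entropy(d))
})
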