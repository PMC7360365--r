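# Shared fixtures and small independent oracles used across the test files.
# Everything is built in code; no data files.

abc_alphabet <- function() {
  monomer_alphabet(c("A", "B", "C"), acceptor_carbons = c(2, 3))
}

blood_alphabet <- function() {
  monomer_alphabet(c("GlcNAc", "Gal", "Fuc"))
}

b_antigen_parts <- function() {
  ab <- blood_alphabet()
  list(
    alphabet = ab,
    input = parse_oligomer("Gal(3-1)GlcNAc", ab),
    h_antigen = parse_oligomer("[Fuc(2-1)]Gal(3-1)GlcNAc", ab),
    b_antigen = parse_oligomer("[Fuc(2-1)][Gal(3-1)]Gal(3-1)GlcNAc", ab),
    fut2_cf = enzyme_rule("Fut2cf", donor_type = "Fuc", acceptor_type = "Gal",
                          acceptor_carbon = 2, class = "cf", alphabet = ab),
    gtb_bs = enzyme_rule("GTBbs", donor_type = "Gal", acceptor_type = "Gal",
                         acceptor_carbon = 3, class = "bs",
                         required_branches = "Fuc(2-1)", alphabet = ab),
    fut2_rs = enzyme_rule("Fut2rs", donor_type = "Fuc", acceptor_type = "Gal",
                          acceptor_carbon = 2, class = "rs",
                          root_chain = "(3-1)GlcNAc", alphabet = ab)
  )
}

# independent structural equality oracle: recursive child-map comparison,
# no serialization involved
trees_identical <- function(a, b, ai = 1L, bi = 1L) {
  if (a$type[ai] != b$type[bi]) return(FALSE)
  ach <- which(!is.na(a$parent) & a$parent == ai)
  bch <- which(!is.na(b$parent) & b$parent == bi)
  if (length(ach) != length(bch)) return(FALSE)
  ach <- ach[order(a$ac[ach])]
  bch <- bch[order(b$ac[bch])]
  for (k in seq_along(ach)) {
    if (a$ac[ach[k]] != b$ac[bch[k]] || a$dc[ach[k]] != b$dc[bch[k]]) {
      return(FALSE)
    }
    if (!trees_identical(a, b, ach[k], bch[k])) return(FALSE)
  }
  TRUE
}

# brute-force sub-oligomer oracle: filter all node subsets for
# connectedness-through-root, then dedup structurally
brute_force_sub_oligomers <- function(target) {
  n <- oligomer_size(target)
  keys <- character(0)
  for (mask in seq_len(2^(n - 1)) - 1L) {
    keep <- c(1L, which(as.logical(bitwAnd(mask, 2^(seq_len(n - 1) - 1L)))) + 1L)
    # connected through root: every kept node's parent is kept
    if (all(is.na(target$parent[keep]) | target$parent[keep] %in% keep)) {
      sub <- glycompart:::induced_oligomer(target, keep)
      keys <- c(keys, serialize_canonical(sub))
    }
  }
  sort(unique(keys))
}

# random compartment + input draw used by the network property suites
draw_compartment_case <- function(alphabet, n_enzymes = sample(2:4, 1),
                                  input_max = 3L) {
  lib <- generate_random_enzyme_library(alphabet, n_enzymes = n_enzymes,
                                        class_probs = c(cf = .5, bs = .5,
                                                        rs = 0))
  list(compartment = compartment(lib, residence_time = Inf),
       input = generate_random_oligomer(alphabet, input_max))
}

# random planning instance small enough for the exhaustive oracle: a target,
# a sub-oligomer input, and a library mixing context-free and ideal
# branch-sensitive realizations of the target's addition steps
draw_planning_instance <- function(alphabet, max_target = 6L) {
  target <- generate_random_oligomer(alphabet, max_size = max_target,
                                     size = sample(3:max_target, 1))
  subs <- enumerate_sub_oligomers(target)
  input <- subs[[sample.int(length(subs) - 1L, 1L)]]
  adds <- glycompart:::missing_additions(input, target)
  lib <- list()
  for (j in unique(adds$node)) {
    row <- adds[adds$node == j, ][1, ]
    if (stats::runif(1) < .85) {
      lib[[length(lib) + 1L]] <- enzyme_rule(
        paste0("cf", j), donor_type = row$donor_type,
        acceptor_type = row$acceptor_type,
        acceptor_carbon = row$acceptor_carbon,
        donor_carbon = row$donor_carbon, class = "cf", alphabet = alphabet)
    }
    if (stats::runif(1) < .6) {
      p <- target$parent[row$node]
      psub <- glycompart:::induced_oligomer(
        target, glycompart:::ancestors_and_self(target, p))
      lib[[length(lib) + 1L]] <- make_ideal_enzyme(
        "bs", psub, node = oligomer_size(psub),
        carbon = row$acceptor_carbon, donor = row$donor_type,
        donor_carbon = row$donor_carbon, name = paste0("bs", j))
    }
  }
  if (length(lib) > 5L) lib <- lib[sample.int(length(lib), 5L)]
  for (k in seq_along(lib)) lib[[k]]$name <- paste0(lib[[k]]$name, "_", k)
  list(input = input, target = target, lib = lib)
}

# single-enzyme-chain feasibility route: a target is synthesizable at all
# iff it is synthesizable through single-enzyme compartments
# (BFS on the sub-oligomer lattice, one enzyme per edge)
feasible_by_single_enzymes <- function(input, target, library, cache = NULL) {
  lattice <- enumerate_sub_oligomers(target)
  keep <- vapply(lattice, function(x) is_sub_oligomer(input, x), logical(1))
  lattice <- lattice[keep]
  keys <- vapply(lattice, serialize_canonical, character(1))
  tkey <- serialize_canonical(target)
  seen <- serialize_canonical(input)
  frontier <- list(input)
  while (length(frontier) > 0L) {
    nxt <- list()
    for (a in frontier) {
      for (bi in seq_along(lattice)) {
        if (keys[bi] %in% seen) next
        if (!is_sub_oligomer(a, lattice[[bi]])) next
        e <- single_enzyme_step(a, lattice[[bi]], library, cache = cache)
        if (!is.null(e)) {
          if (keys[bi] == tkey) return(TRUE)
          seen <- c(seen, keys[bi])
          nxt[[length(nxt) + 1L]] <- lattice[[bi]]
        }
      }
    }
    frontier <- nxt
  }
  FALSE
}
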