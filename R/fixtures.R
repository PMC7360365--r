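#' Generate a random oligomer
#'
#' Grows a random rooted tree by repeatedly attaching a uniformly chosen
#' monomer type at a uniformly chosen free site, up to a size drawn
#' uniformly from 1..`max_size` (or exactly `size` if given). Deterministic
#' for a given seed.
#'
#' @param alphabet A [monomer_alphabet()].
#' @param max_size Maximum monomer count.
#' @param size Optional exact size.
#' @param seed Optional integer seed.
#' @return A `glyc_oligomer`.
#' @export
generate_random_oligomer <- function(alphabet, max_size = 6L, size = NULL,
                                     seed = NULL) {
  stopifnot(inherits(alphabet, "glyc_alphabet"), max_size >= 1L)
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
  }
  size <- size %||% sample.int(max_size, 1L)
  types <- names(alphabet)
  o <- oligomer(types[sample.int(length(types), 1L)], alphabet)
  while (oligomer_size(o) < size) {
    sites <- free_sites(o)
    if (nrow(sites) == 0L) break
    si <- sample.int(nrow(sites), 1L)
    donor <- types[sample.int(length(types), 1L)]
    o <- add_monomer(o, node = sites$node[si], carbon = sites$carbon[si],
                     donor = donor)
  }
  o
}

#' Generate a random enzyme library
#'
#' Draws GTase rules with uniformly random donor/acceptor types and carbons.
#' Classes are drawn from `class_probs`. Branch-sensitive rules receive, with
#' probability `p_required`, one required branch (a random single-monomer
#' pattern on another carbon) and, with probability `p_forbidden`, one
#' wildcard-forbidden carbon. Root-sensitive rules receive a random root
#' chain of length 0–2. Deterministic for a given seed.
#'
#' @param alphabet A [monomer_alphabet()].
#' @param n_enzymes Number of rules.
#' @param class_probs Named probabilities for classes `cf`, `bs`, `rs`.
#' @param p_required,p_forbidden Branch-constraint probabilities
#'   (branch-sensitive rules only).
#' @param seed Optional integer seed.
#' @return A list of `glyc_enzyme`s named `E1`, `E2`, ...
#' @export
generate_random_enzyme_library <- function(alphabet, n_enzymes = 3L,
                                           class_probs = c(cf = 0.5, bs = 0.5,
                                                           rs = 0),
                                           p_required = 0.6,
                                           p_forbidden = 0.2,
                                           seed = NULL) {
  stopifnot(inherits(alphabet, "glyc_alphabet"), n_enzymes >= 1L)
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
  }
  types <- names(alphabet)
  classes <- c(cf = "context_free", bs = "branch_sensitive",
               rs = "root_sensitive")
  probs <- rlang::set_names(rep(0, 3), names(classes))
  probs[names(class_probs)] <- class_probs
  lapply(seq_len(n_enzymes), function(i) {
    cls <- classes[[sample(names(classes), 1L, prob = probs)]]
    acceptor <- types[sample.int(length(types), 1L)]
    acc_carbons <- alphabet[[acceptor]]$acceptor_carbons
    carbon <- acc_carbons[sample.int(length(acc_carbons), 1L)]
    donor <- types[sample.int(length(types), 1L)]
    required <- list(); forbidden <- list(); chain <- list()
    if (cls == "branch_sensitive") {
      others <- setdiff(acc_carbons, carbon)
      if (length(others) > 0L && stats::runif(1) < p_required) {
        bc <- others[sample.int(length(others), 1L)]
        pt <- types[sample.int(length(types), 1L)]
        required <- list(list(carbon = bc,
                              dc = alphabet[[pt]]$donor_carbon,
                              pattern = oligomer(pt, alphabet)))
        others <- setdiff(others, bc)
      }
      if (length(others) > 0L && stats::runif(1) < p_forbidden) {
        fc <- others[sample.int(length(others), 1L)]
        forbidden <- list(list(carbon = fc, pattern = "*"))
      }
    } else if (cls == "root_sensitive") {
      len <- sample(0:2, 1L)
      cur_child <- acceptor
      for (d in seq_len(len)) {
        pt <- types[sample.int(length(types), 1L)]
        pcs <- alphabet[[pt]]$acceptor_carbons
        chain <- c(chain, list(list(
          ac = pcs[sample.int(length(pcs), 1L)],
          dc = alphabet[[cur_child]]$donor_carbon, type = pt)))
        cur_child <- pt
      }
    }
    enzyme_rule(paste0("E", i), donor_type = donor, acceptor_type = acceptor,
                acceptor_carbon = carbon, class = cls,
                required_branches = required, forbidden_branches = forbidden,
                root_chain = chain, alphabet = alphabet)
  })
}

#' Built-in scenario fixtures
#'
#' Ready-made model scenarios used throughout the documentation and tests.
#' All enzyme sets are synthetic reconstructions chosen to exhibit the named
#' behavior; they are not fitted to measured glycomics data.
#'
#' * `"b_antigen"` — blood-group B antigen synthesis: a context-free
#'   fucosyltransferase (Fut2-like) and a branch-sensitive
#'   galactosyltransferase (GTB-like, requiring the fucose branch). In one
#'   shared compartment the pair sets up a runaway loop (tandem Gal repeats);
#'   split across two compartments they specifically synthesize the
#'   B antigen from the Gal-GlcNAc precursor.
#' * `"mucin_like"` — truncated profile: a divergent two-stage upstream
#'   (three inputs in a 1:1:2 ratio, entropy 1.5 bits) feeding a convergent
#'   final compartment probed at short residence time, so intermediate
#'   oligomers exit alongside terminals.
#' * `"human_cg_like"` — mutually-exclusive-fates profile: the same
#'   divergent upstream, with the final compartment run at long residence
#'   time so intermediates converge onto few terminals.
#' * `"horse_cg_like"` — tandem-repeat profile: a unique input enters a
#'   final compartment whose two enzymes form a linkage loop
#'   (poly-LacNAc-style runaway), keeping entropy high at long residence
#'   times.
#'
#' @param name Fixture name; `NULL` lists available names.
#' @return A list with elements `name`, `description`, `status`, `alphabet`,
#'   `input` (oligomer), `series` (list of compartments), and for
#'   `"b_antigen"` also `library` and `target`.
#' @export
builtin_fixtures <- function(name = NULL) {
  fixtures <- list(
    b_antigen = fixture_b_antigen,
    mucin_like = fixture_mucin_like,
    human_cg_like = fixture_human_cg_like,
    horse_cg_like = fixture_horse_cg_like
  )
  if (is.null(name)) return(names(fixtures))
  if (!name %in% names(fixtures)) {
    stop("unknown fixture: ", name, "; available: ",
         paste(names(fixtures), collapse = ", "), call. = FALSE)
  }
  fixtures[[name]]()
}

fixture_b_antigen <- function() {
  ab <- monomer_alphabet(c("GlcNAc", "Gal", "Fuc"))
  fut2 <- enzyme_rule("Fut2cf", donor_type = "Fuc", acceptor_type = "Gal",
                      acceptor_carbon = 2, class = "cf", alphabet = ab)
  gtb <- enzyme_rule("GTBbs", donor_type = "Gal", acceptor_type = "Gal",
                     acceptor_carbon = 3, class = "bs",
                     required_branches = "Fuc(2-1)", alphabet = ab)
  list(
    name = "b_antigen",
    description = paste("Blood-group B antigen from the Gal-GlcNAc precursor:",
                        "context-free fucosyltransferase plus branch-sensitive",
                        "galactosyltransferase; synthetic reconstruction."),
    status = "reconstruction",
    alphabet = ab,
    input = parse_oligomer("Gal(3-1)GlcNAc", ab),
    target = parse_oligomer("[Fuc(2-1)][Gal(3-1)]Gal(3-1)GlcNAc", ab),
    library = list(fut2, gtb),
    series = list(compartment(fut2, Inf), compartment(gtb, Inf)),
    single_compartment = compartment(list(fut2, gtb), Inf)
  )
}

# divergent upstream shared by the mucin-like and human-CG-like scenarios:
# produces three oligomers in a 1:1:2 ratio (entropy 1.5 bits)
upstream_divergent <- function(ab) {
  galt3 <- enzyme_rule("GalT3", donor_type = "Gal", acceptor_type = "GalNAc",
                       acceptor_carbon = 3, class = "cf", alphabet = ab)
  gnt3 <- enzyme_rule("GnT3", donor_type = "GlcNAc", acceptor_type = "GalNAc",
                      acceptor_carbon = 3, class = "cf", alphabet = ab)
  galt6 <- enzyme_rule("GalT6", donor_type = "Gal", acceptor_type = "GalNAc",
                       acceptor_carbon = 6, class = "bs",
                       required_branches = "Gal(3-1)", alphabet = ab)
  gnt6 <- enzyme_rule("GnT6", donor_type = "GlcNAc", acceptor_type = "GalNAc",
                      acceptor_carbon = 6, class = "bs",
                      required_branches = "Gal(3-1)", alphabet = ab)
  list(compartment(list(galt3, gnt3), Inf),
       compartment(list(galt6, gnt6), Inf))
}

fixture_mucin_like <- function() {
  ab <- monomer_alphabet(c("GalNAc", "Gal", "GlcNAc", "Fuc"))
  final <- compartment(list(
    enzyme_rule("GalT4", donor_type = "Gal", acceptor_type = "GlcNAc",
                acceptor_carbon = 4, class = "cf", alphabet = ab),
    enzyme_rule("FucT2", donor_type = "Fuc", acceptor_type = "Gal",
                acceptor_carbon = 2, class = "cf", alphabet = ab)
  ), residence_time = 1)
  list(
    name = "mucin_like",
    description = paste("Truncated-convergent profile: divergent upstream",
                        "(1:1:2 inputs, 1.5 bits) feeding a convergent chain-",
                        "extension compartment probed at short residence time;",
                        "synthetic reconstruction."),
    status = "reconstruction",
    alphabet = ab,
    input = oligomer("GalNAc", ab),
    series = c(upstream_divergent(ab), list(final))
  )
}

fixture_human_cg_like <- function() {
  fx <- fixture_mucin_like()
  fx$name <- "human_cg_like"
  fx$description <- paste("Mutually-exclusive-fates profile: the same",
                          "divergent upstream, final compartment run at long",
                          "residence time so intermediates converge onto few",
                          "terminals; synthetic reconstruction.")
  fx$series[[3]]$residence_time <- 50
  fx
}

fixture_horse_cg_like <- function() {
  ab <- monomer_alphabet(c("GalNAc", "Gal", "GlcNAc", "Fuc"))
  stage1 <- compartment(
    enzyme_rule("GnT3", donor_type = "GlcNAc", acceptor_type = "GalNAc",
                acceptor_carbon = 3, class = "cf", alphabet = ab),
    residence_time = Inf
  )
  final <- compartment(list(
    enzyme_rule("GalT4", donor_type = "Gal", acceptor_type = "GlcNAc",
                acceptor_carbon = 4, class = "cf", alphabet = ab),
    enzyme_rule("GnT3Gal", donor_type = "GlcNAc", acceptor_type = "Gal",
                acceptor_carbon = 3, class = "cf", alphabet = ab)
  ), residence_time = 5)
  list(
    name = "horse_cg_like",
    description = paste("Tandem-repeat profile: unique input, final",
                        "compartment with a GlcNAc-Gal linkage loop driving",
                        "poly-LacNAc-style runaway growth; synthetic",
                        "reconstruction."),
    status = "reconstruction",
    alphabet = ab,
    input = oligomer("GalNAc", ab),
    series = list(stage1, final)
  )
}
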