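#' Output distributions over oligomers
#'
#' An output distribution assigns probabilities to the oligomers exiting a
#' compartment (or series). It is a tibble with columns `oligomer`
#' (canonical string) and `probability`, carrying the oligomer objects, the
#' computation method (`"exact"` or `"monte_carlo"`), and, for Monte Carlo,
#' the sample count and seed, as attributes.
#'
#' @param oligomers A list of `glyc_oligomer`s (or a single one).
#' @param probabilities Numeric vector summing to 1; defaults to a point
#'   mass when a single oligomer is given.
#' @param method,n_samples,seed Provenance metadata.
#' @return A `glyc_distribution`.
#' @examples
#' ab <- monomer_alphabet(c("Gal", "GlcNAc"))
#' d <- output_distribution(list(oligomer("Gal", ab), oligomer("GlcNAc", ab)),
#'                          c(0.5, 0.5))
#' shannon_entropy(d)
#' @export
output_distribution <- function(oligomers, probabilities = NULL,
                                method = "exact", n_samples = NULL,
                                seed = NULL) {
  if (inherits(oligomers, "glyc_oligomer")) oligomers <- list(oligomers)
  stopifnot(all(vapply(oligomers, inherits, logical(1), "glyc_oligomer")))
  probabilities <- probabilities %||% rep(1 / length(oligomers),
                                          length(oligomers))
  stopifnot(length(probabilities) == length(oligomers))
  keys <- vapply(oligomers, serialize_canonical, character(1))
  # merge structurally equal support points
  agg <- rowsum(probabilities, keys)
  ukeys <- rownames(agg)
  olist <- rlang::set_names(oligomers[match(ukeys, keys)], ukeys)
  p <- as.numeric(agg)
  if (abs(sum(p) - 1) > 1e-9 || any(p < -1e-12)) {
    stop("probabilities must be in [0,1] and sum to 1", call. = FALSE)
  }
  p <- pmax(p, 0)
  out <- tibble::tibble(oligomer = ukeys, probability = p)
  out <- out[order(-out$probability, out$oligomer), ]
  structure(out,
            oligomers = olist[out$oligomer],
            method = method, n_samples = n_samples, seed = seed,
            class = c("glyc_distribution", class(out)))
}

#' @export
print.glyc_distribution <- function(x, ...) {
  cat("<glyc_distribution> ", nrow(x), " oligomers (", attr(x, "method"),
      "), entropy ", format(round(shannon_entropy(x), 4)), " bits\n", sep = "")
  NextMethod()
}

support_oligomers <- function(d, tol = 1e-12) {
  attr(d, "oligomers")[d$probability > tol]
}

#' @method tidy glyc_distribution
#' @export
tidy.glyc_distribution <- function(x, ...) {
  tibble::tibble(oligomer = x$oligomer, probability = x$probability,
                 size = vapply(attr(x, "oligomers"), oligomer_size, integer(1)))
}

#' @method glance glyc_distribution
#' @export
glance.glyc_distribution <- function(x, ...) {
  tibble::tibble(
    n_oligomers = sum(x$probability > 1e-12),
    entropy_bits = shannon_entropy(x),
    method = attr(x, "method"),
    n_samples = attr(x, "n_samples") %||% NA_integer_,
    seed = attr(x, "seed") %||% NA_integer_
  )
}

#' Shannon entropy of an output distribution, in bits
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} with \eqn{0 \log 0 = 0}. The entropy of
#' a glycan profile is, approximately, the log2 of the number of distinct
#' high-abundance oligomers: 0 for a uniquely synthesized product, 1.5 for
#' three products in a 1:1:2 ratio, 2 for four equally likely products.
#'
#' @param d A `glyc_distribution`, or a bare numeric vector of
#'   probabilities.
#' @return Entropy in bits (nonnegative scalar).
#' @export
shannon_entropy <- function(d) {
  p <- if (is.numeric(d)) d else d$probability
  p <- p[p > 0]
  if (abs(sum(p) - 1) > 1e-6) {
    stop("probabilities must sum to 1", call. = FALSE)
  }
  max(0, -sum(p * log2(p))) # max() guards the negative zero of -0 * log2(1)
}

# expand a reaction network from several input oligomers at once
union_reaction_network <- function(c, inputs, size_cap, max_states = 500L) {
  nets <- lapply(inputs, function(o) {
    build_reaction_network(c, o, size_cap = size_cap, max_states = max_states)
  })
  states <- list(); edges <- list(); terminal <- character(0)
  clipped <- character(0); truncated <- FALSE
  for (nt in nets) {
    states <- c(states, nt$states[setdiff(names(nt$states), names(states))])
    edges <- c(edges, list(nt$edges))
    terminal <- union(terminal, nt$terminal)
    clipped <- union(clipped, nt$clipped)
    truncated <- truncated || nt$truncated
  }
  if (length(states) > max_states) {
    stop("reaction state space exceeds max_states (", max_states, ")",
         call. = FALSE)
  }
  edges <- dplyr::distinct(dplyr::bind_rows(edges))
  list(states = states, edges = edges, terminal = terminal,
       clipped = clipped, truncated = truncated)
}

#' Exact output distribution of a compartment
#'
#' Stochastic assembly is a continuous-time Markov chain over the reaction
#' network: each matching (enzyme, site) pair fires independently with
#' propensity equal to the enzyme concentration. The exit distribution is
#' computed in closed form from the generator matrix Q:
#'
#' * `transport` exit (exponential residence, mean T, rate r = 1/T):
#'   the exit state distribution is \eqn{r\,p_0^\top (rI - Q)^{-1}}
#'   (the resolvent of the generator).
#' * `maturation` exit (fixed residence T): \eqn{p_0^\top e^{QT}}
#'   (matrix exponential).
#' * `T = Inf`: all probability mass is absorbed into terminal states
#'   (fundamental-matrix absorption probabilities).
#'
#' The map is linear in the input distribution. If the reaction network hits
#' the size cap (runaway growth), an infinite residence time is an error;
#' at finite T the computation proceeds on the capped state space (states at
#' the cap become absorbing) and the result is flagged approximate.
#'
#' @param c A [compartment()].
#' @param input_dist A `glyc_distribution` or a single `glyc_oligomer`.
#' @param size_cap Maximum oligomer size enumerated; default input size + 24.
#' @param max_states State-space cap for the exact method (default 500);
#'   exceeding it is an error (fall back to [simulate_compartment()]).
#' @param warn_truncated Warn when computing on a cap-clipped network.
#' @return A `glyc_distribution` with method `"exact"`.
#' @export
exact_output_distribution <- function(c, input_dist, size_cap = NULL,
                                      max_states = 500L,
                                      warn_truncated = TRUE) {
  stopifnot(inherits(c, "glyc_compartment"))
  if (inherits(input_dist, "glyc_oligomer")) {
    input_dist <- output_distribution(input_dist)
  }
  inputs <- support_oligomers(input_dist)
  size_cap <- size_cap %||%
    (max(vapply(inputs, oligomer_size, integer(1))) + 24L)
  net <- union_reaction_network(c, inputs, size_cap, max_states)
  if (net$truncated) {
    if (is.infinite(c$residence_time)) {
      stop("runaway reaction reachable with infinite residence time: ",
           "the output distribution does not exist", call. = FALSE)
    }
    if (warn_truncated) {
      warning("reaction network clipped at size cap ", size_cap,
              "; exit distribution is approximate", call. = FALSE)
    }
  }
  keys <- names(net$states)
  nst <- length(keys)
  idx <- rlang::set_names(seq_len(nst), keys)
  Q <- matrix(0, nst, nst)
  if (nrow(net$edges) > 0L) {
    for (r in seq_len(nrow(net$edges))) {
      i <- idx[[net$edges$from[r]]]
      j <- idx[[net$edges$to[r]]]
      Q[i, j] <- Q[i, j] + net$edges$rate[r]
    }
    diag(Q) <- diag(Q) - rowSums(Q)
  }
  p0 <- numeric(nst)
  p0[idx[input_dist$oligomer]] <- input_dist$probability
  Tres <- c$residence_time
  p_exit <- if (is.infinite(Tres)) {
    absorbing <- vapply(seq_len(nst), function(i) all(Q[i, -i] == 0), logical(1))
    trans <- which(!absorbing)
    absi <- which(absorbing)
    p <- numeric(nst)
    p[absi] <- p0[absi]
    if (length(trans) > 0L) {
      B <- solve(-Q[trans, trans, drop = FALSE], Q[trans, absi, drop = FALSE])
      p[absi] <- p[absi] + as.numeric(p0[trans] %*% B)
    }
    p
  } else if (c$exit_model == "transport") {
    r <- 1 / Tres
    A <- r * diag(nst) - Q
    as.numeric(solve(t(A), r * p0))
  } else {
    E <- as.matrix(Matrix::expm(Matrix::Matrix(Q * Tres)))
    as.numeric(p0 %*% E)
  }
  p_exit <- pmax(p_exit, 0)
  p_exit <- p_exit / sum(p_exit)
  keep <- p_exit > 1e-15
  out <- output_distribution(net$states[keep], p_exit[keep], method = "exact")
  attr(out, "approximate") <- net$truncated
  out
}
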