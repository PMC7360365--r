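#' Monte Carlo simulation of a compartment
#'
#' Simulates individual oligomer trajectories through the compartment with
#' the Gillespie algorithm: while the oligomer is inside, every matching
#' (enzyme, site) pair fires with propensity equal to the enzyme
#' concentration; waiting times are exponential in the total propensity.
#' Exit follows the compartment's exit model — under `transport` an
#' independent exponential exit clock with mean T (equivalently, an extra
#' reaction channel of rate 1/T); under `maturation` a hard time horizon T.
#' With `T = Inf` each trajectory runs to a terminal oligomer.
#'
#' @param c A [compartment()].
#' @param input_dist A `glyc_distribution` or single `glyc_oligomer`; each
#'   trajectory draws its starting oligomer from this distribution.
#' @param n_samples Number of trajectories.
#' @param seed Integer seed; the run is reproducible given the seed, which
#'   is recorded in the result.
#' @param max_steps Safety limit on additions per trajectory (guards
#'   `T = Inf` with runaway compartments).
#' @return A `glyc_distribution` with method `"monte_carlo"`.
#' @export
simulate_compartment <- function(c, input_dist, n_samples = 1000L,
                                 seed = NULL, max_steps = 10000L) {
  stopifnot(inherits(c, "glyc_compartment"), n_samples >= 1L)
  if (inherits(input_dist, "glyc_oligomer")) {
    input_dist <- output_distribution(input_dist)
  }
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
  }
  inputs <- attr(input_dist, "oligomers")
  starts <- sample.int(nrow(input_dist), n_samples, replace = TRUE,
                       prob = input_dist$probability)
  out_keys <- character(n_samples)
  out_oligos <- new.env(parent = emptyenv())
  for (tr in seq_len(n_samples)) {
    o <- inputs[[starts[tr]]]
    o <- simulate_trajectory(c, o, max_steps)
    k <- serialize_canonical(o)
    out_keys[tr] <- k
    if (!exists(k, envir = out_oligos, inherits = FALSE)) {
      assign(k, o, envir = out_oligos)
    }
  }
  tab <- table(out_keys)
  keys <- names(tab)
  output_distribution(lapply(keys, get, envir = out_oligos),
                      as.numeric(tab) / n_samples,
                      method = "monte_carlo", n_samples = n_samples,
                      seed = seed)
}

# One Gillespie trajectory. Site matches are tracked incrementally: an
# addition at parent p only changes matches at the new leaf, at p (carbon
# occupancy), and — for branch-sensitive enzymes, whose patterns are exact
# full subtrees — at ancestors within the largest pattern size of the new
# leaf (farther ancestors hold that branch at a size already beyond every
# pattern, so their match status through it cannot change).
simulate_trajectory <- function(c, o, max_steps) {
  Tres <- c$residence_time
  enz <- unname(c$enzymes)
  ne <- length(enz)
  conc <- vapply(enz, function(e) e$concentration, numeric(1))
  maxpat <- 0L
  for (e in enz) {
    for (b in c(e$required_branches, e$forbidden_branches)) {
      if (!identical(b$pattern, "*")) {
        maxpat <- max(maxpat, oligomer_size(b$pattern))
      }
    }
  }
  bs_present <- any(vapply(enz, function(e) e$class == "branch_sensitive",
                           logical(1)))
  # matches[[k]]: integer vector of node ids where enzyme k can act
  matches <- lapply(enz, function(e) match_nodes(e, o))
  t_now <- 0
  exit_rate <- if (c$exit_model == "transport" && is.finite(Tres)) 1 / Tres else 0
  for (step in seq_len(max_steps)) {
    counts <- lengths(matches)
    rates <- counts * conc
    total_r <- sum(rates)
    if (total_r == 0) return(o) # terminal
    if (is.finite(Tres) || exit_rate > 0) {
      dt <- stats::rexp(1, total_r + exit_rate)
      if (c$exit_model == "maturation" && t_now + dt > Tres) return(o)
      t_now <- t_now + dt
      if (stats::runif(1) * (total_r + exit_rate) > total_r) return(o)
    }
    k <- sample.int(ne, 1L, prob = rates)
    node <- matches[[k]][sample.int(counts[k], 1L)]
    e <- enz[[k]]
    o <- add_monomer(o, node = node, carbon = e$acceptor_carbon,
                     donor = e$donor_type, donor_carbon = e$donor_carbon)
    new_id <- oligomer_size(o)
    affected <- c(new_id, node)
    if (bs_present && maxpat > 0L) {
      a <- o$parent[node]
      hops <- 1L
      while (!is.na(a) && hops <= maxpat) {
        affected <- c(affected, a)
        a <- o$parent[a]
        hops <- hops + 1L
      }
    }
    for (kk in seq_len(ne)) {
      m <- setdiff(matches[[kk]], affected)
      hit <- affected[vapply(affected, function(i) {
        node_matches(enz[[kk]], o, i)
      }, logical(1))]
      matches[[kk]] <- c(m, hit)
    }
  }
  stop("trajectory exceeded max_steps (", max_steps,
       "); runaway growth with no exit?", call. = FALSE)
}

#' Run an oligomer through a series of compartments
#'
#' Composes the compartment maps in order: the output distribution of stage
#' k is the input distribution of stage k+1; the final output is the glycan
#' profile of the series. An empty series is the identity.
#'
#' @param series A list of [compartment()]s (or a single compartment).
#' @param input A `glyc_oligomer` or `glyc_distribution`.
#' @param method `"exact"` (default), `"monte_carlo"`, or `"auto"` (exact
#'   unless a stage's network is runaway/too large, then Monte Carlo).
#' @param n_samples,seed Monte Carlo parameters.
#' @param size_cap,max_states Exact-method parameters (per stage).
#' @return The final `glyc_distribution`.
#' @export
run_series <- function(series, input, method = c("exact", "monte_carlo", "auto"),
                       n_samples = 4000L, seed = NULL, size_cap = NULL,
                       max_states = 500L) {
  series <- as_series(series)
  method <- match.arg(method)
  dist <- if (inherits(input, "glyc_distribution")) input else {
    output_distribution(input)
  }
  for (k in seq_along(series)) {
    cpt <- series[[k]]
    stage_seed <- if (is.null(seed)) NULL else seed + k
    dist <- switch(method,
      exact = exact_output_distribution(cpt, dist, size_cap = size_cap,
                                        max_states = max_states),
      monte_carlo = simulate_compartment(cpt, dist, n_samples = n_samples,
                                         seed = stage_seed),
      auto = {
        ex <- tryCatch(
          exact_output_distribution(cpt, dist, size_cap = size_cap,
                                    max_states = max_states,
                                    warn_truncated = FALSE),
          error = function(err) NULL
        )
        if (is.null(ex) || isTRUE(attr(ex, "approximate"))) {
          simulate_compartment(cpt, dist, n_samples = n_samples,
                               seed = stage_seed)
        } else {
          ex
        }
      }
    )
  }
  dist
}

#' Entropy of the series output as a function of residence time
#'
#' Recomputes the final output distribution of a compartment series while
#' sweeping the residence time T of one stage (by convention the last; all
#' other stages are run at their configured times, typically `Inf`), and
#' records the Shannon entropy at each T. The resulting curve is the
#' standard diagnostic of how variability depends on residence time: with
#' truncated-convergent kinetics entropy rises at short T (intermediates
#' exit) and falls at long T (intermediates converge onto few terminals);
#' with runaway kinetics it keeps growing (tandem repeats).
#'
#' @param series List of [compartment()]s.
#' @param input `glyc_oligomer` or `glyc_distribution`.
#' @param T_grid Positive residence times to probe.
#' @param which_stage Index of the probed stage; default the last.
#' @param method,n_samples,seed,size_cap,max_states As in [run_series()];
#'   default method `"auto"` switches to Monte Carlo for runaway stages.
#' @return A `glyc_entropy_curve`: tibble with columns `T` and
#'   `entropy_bits`.
#' @export
entropy_curve <- function(series, input, T_grid, which_stage = NULL,
                          method = "auto", n_samples = 4000L, seed = NULL,
                          size_cap = NULL, max_states = 500L) {
  series <- as_series(series)
  which_stage <- which_stage %||% length(series)
  stopifnot(which_stage >= 1L, which_stage <= length(series),
            all(T_grid > 0))
  ent <- vapply(seq_along(T_grid), function(i) {
    s2 <- series
    s2[[which_stage]]$residence_time <- T_grid[i]
    d <- run_series(s2, input, method = method, n_samples = n_samples,
                    seed = if (is.null(seed)) NULL else seed + 1000L * i,
                    size_cap = size_cap, max_states = max_states)
    shannon_entropy(d)
  }, numeric(1))
  out <- tibble::tibble(T = as.numeric(T_grid), entropy_bits = ent)
  structure(out, which_stage = which_stage,
            class = c("glyc_entropy_curve", class(out)))
}
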