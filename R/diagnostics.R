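#' Is a compartment algorithmic for a given input?
#'
#' An algorithmic compartment maps each input to a unique output: no runaway
#' loops are reachable and the finite reaction network from the input has
#' exactly one terminal state. At infinite residence time such a compartment
#' specifically synthesizes that terminal, with zero output entropy.
#'
#' @param c A [compartment()].
#' @param input A `glyc_oligomer`.
#' @param size_cap Expansion bound used to enumerate the (finite) network.
#' @param max_states State-count bound.
#' @return A list with `algorithmic` (logical) and `output` (the unique
#'   terminal `glyc_oligomer`, or `NULL`).
#' @export
is_algorithmic_compartment <- function(c, input, size_cap = NULL,
                                       max_states = 50000L) {
  stopifnot(inherits(c, "glyc_compartment"), inherits(input, "glyc_oligomer"))
  if (length(detect_runaway(c, input)) > 0L) {
    return(list(algorithmic = FALSE, output = NULL))
  }
  size_cap <- size_cap %||% (oligomer_size(input) + 48L)
  net <- build_reaction_network(c, input, size_cap, max_states = max_states)
  if (net$truncated) {
    # network outgrew the cap without a detected loop; treat as not
    # algorithmic (cannot certify a unique terminal)
    return(list(algorithmic = FALSE, output = NULL))
  }
  if (length(net$terminal) == 1L) {
    list(algorithmic = TRUE, output = net$states[[net$terminal]])
  } else {
    list(algorithmic = FALSE, output = NULL)
  }
}

#' Reduce a compartment to an algorithmic one
#'
#' Removes enzymes until the linkage network has no active loops and no
#' acceptor blocks remain, then sets the residence time to infinity:
#' runaway reactions are eliminated by breaking every linkage loop (or
#' relying on triggers that disable branch-sensitive edges), divergent
#' reactions by keeping at most one enzyme of every blocked pair, truncated
#' reactions by the infinite residence time. Removal is greedy and
#' deterministic: the enzyme involved in the most loops and blocks is
#' dropped first, ties broken by name.
#'
#' @param c A [compartment()].
#' @return A `glyc_compartment` with `residence_time = Inf` whose enzyme
#'   subset has no active loops and no blocks (possibly empty in the
#'   degenerate case of a single self-looping enzyme).
#' @export
make_algorithmic <- function(c) {
  stopifnot(inherits(c, "glyc_compartment"))
  enzymes <- c$enzymes
  repeat {
    if (length(enzymes) == 0L) break
    cur <- compartment(unname(enzymes), residence_time = Inf,
                       exit_model = c$exit_model)
    loops <- detect_runaway(cur)
    blocks <- detect_acceptor_blocks(cur)
    if (length(loops) == 0L && nrow(blocks) == 0L) break
    involvement <- rlang::set_names(numeric(length(enzymes)), names(enzymes))
    for (cyc in loops) {
      for (nm in unique(unlist(cyc$enzymes))) {
        involvement[nm] <- involvement[nm] + 1
      }
    }
    for (r in seq_len(nrow(blocks))) {
      involvement[blocks$blocker[r]] <- involvement[blocks$blocker[r]] + 1
      involvement[blocks$blocked[r]] <- involvement[blocks$blocked[r]] + 1
    }
    # deterministic tie-break: highest involvement, then lexicographic name
    top <- involvement[involvement == max(involvement)]
    drop <- sort(names(top))[1L]
    enzymes <- enzymes[names(enzymes) != drop]
  }
  compartment(unname(enzymes), residence_time = Inf, exit_model = c$exit_model)
}

#' Classify the causes of variability in a compartment series
#'
#' Diagnoses the three — and only three — ways a stochastic assembly line
#' produces variable output:
#'
#' * truncated reactions: a finite residence time lets intermediate
#'   oligomers exit before reaching a terminal state;
#' * runaway reactions: a linkage-network loop generates unbounded tandem
#'   repeats;
#' * divergent reactions: enzymes blocking each other create forks that
#'   never reconverge, so identical inputs reach mutually exclusive fates.
#'
#' @param series A list of [compartment()]s (or one compartment).
#' @param input A `glyc_oligomer`.
#' @param size_cap Oligomer-size bound for per-stage network expansion;
#'   default input size + 12.
#' @param max_states State cap per stage for the exact distribution.
#' @return A `glyc_variability` object: list with `causes` (character
#'   subset of `c("truncated", "runaway", "divergent")`), `loops`,
#'   `blocks`, `divergences`, `truncation` (logical) and a per-stage tibble
#'   `stages`.
#' @export
classify_variability <- function(series, input, size_cap = NULL,
                                 max_states = 2000L) {
  series <- as_series(series)
  stopifnot(inherits(input, "glyc_oligomer"))
  size_cap <- size_cap %||% (oligomer_size(input) + 12L)
  dist <- output_distribution(input)
  causes <- character(0)
  all_loops <- list(); all_divs <- list(); all_blocks <- list()
  truncation <- FALSE
  stage_rows <- list()
  for (k in seq_along(series)) {
    cpt <- series[[k]]
    supports <- support_oligomers(dist, tol = 1e-9)
    loops_k <- list(); div_k <- 0L
    for (o in supports) {
      loops <- detect_runaway(cpt, o)
      loops_k <- c(loops_k, loops)
      net <- build_reaction_network(cpt, o, size_cap,
                                    max_states = max_states)
      div <- detect_divergence(net)
      div_k <- div_k + nrow(div)
      if (nrow(div) > 0L) all_divs <- c(all_divs, list(div))
    }
    blocks <- detect_acceptor_blocks(cpt)
    if (nrow(blocks) > 0L) all_blocks <- c(all_blocks, list(blocks))
    runaway_k <- length(loops_k) > 0L
    if (runaway_k) {
      causes <- union(causes, "runaway")
      all_loops <- c(all_loops, loops_k)
    }
    if (div_k > 0L) causes <- union(causes, "divergent")
    # propagate the distribution; with runaway and T = Inf the exact map
    # does not exist, so run the capped approximation for diagnosis only
    dist <- if (runaway_k && is.infinite(cpt$residence_time)) {
      suppressWarnings(
        exact_output_distribution(
          compartment(unname(cpt$enzymes), residence_time = 1e6,
                      exit_model = cpt$exit_model),
          dist, size_cap = size_cap, max_states = max_states,
          warn_truncated = FALSE)
      )
    } else {
      suppressWarnings(
        exact_output_distribution(cpt, dist, size_cap = size_cap,
                                  max_states = max_states,
                                  warn_truncated = FALSE)
      )
    }
    trunc_k <- FALSE
    if (is.finite(cpt$residence_time)) {
      # does any non-terminal oligomer carry exit mass?
      outs <- support_oligomers(dist, tol = 1e-9)
      for (o in outs) {
        if (has_any_site(cpt, o)) {
          trunc_k <- TRUE
          break
        }
      }
    }
    if (trunc_k) {
      truncation <- TRUE
      causes <- union(causes, "truncated")
    }
    stage_rows[[k]] <- tibble::tibble(
      stage = k, residence_time = cpt$residence_time,
      n_enzymes = length(cpt$enzymes), runaway = runaway_k,
      divergent = div_k > 0L, truncated = trunc_k
    )
  }
  structure(
    list(causes = causes, loops = all_loops,
         blocks = if (length(all_blocks)) dplyr::bind_rows(all_blocks)
                  else tibble::tibble(blocker = character(0),
                                      blocked = character(0),
                                      direction = character(0)),
         divergences = all_divs, truncation = truncation,
         stages = dplyr::bind_rows(stage_rows)),
    class = "glyc_variability"
  )
}

has_any_site <- function(c, o) {
  for (e in c$enzymes) {
    if (length(match_nodes(e, o)) > 0L) return(TRUE)
  }
  FALSE
}

#' @export
print.glyc_variability <- function(x, ...) {
  cat("<glyc_variability> causes: ",
      if (length(x$causes)) paste(x$causes, collapse = ", ") else "(none)",
      "\n", sep = "")
  print(x$stages)
  invisible(x)
}

#' @method tidy glyc_variability
#' @export
tidy.glyc_variability <- function(x, ...) x$stages

#' @method glance glyc_variability
#' @export
glance.glyc_variability <- function(x, ...) {
  tibble::tibble(
    truncated = "truncated" %in% x$causes,
    runaway = "runaway" %in% x$causes,
    divergent = "divergent" %in% x$causes,
    n_loops = length(x$loops),
    n_blocks = nrow(x$blocks)
  )
}
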