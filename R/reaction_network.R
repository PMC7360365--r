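#' Build the reaction network of a compartment
#'
#' The reaction network is the directed graph of every oligomer state
#' reachable from the input by single-monomer additions catalyzed by the
#' compartment's enzymes, in every possible order. Nodes are deduplicated by
#' canonical string; growth is monotone in size, so the network is acyclic.
#' Expansion stops at oligomers of size `size_cap`: if any state at the cap
#' still admits an addition, the network is marked truncated (the compartment
#' supports unbounded, runaway growth or simply outgrew the cap).
#'
#' @param c A [compartment()].
#' @param input A `glyc_oligomer`.
#' @param size_cap Maximum oligomer size to expand (monomer count);
#'   must be at least the input size.
#' @param max_states Safety cap on the number of distinct states explored.
#' @param stop_on_truncation If `TRUE`, expansion stops as soon as the size
#'   cap is first hit; the returned network is then partial but the
#'   `truncated` flag is authoritative. Used for fast boundedness probes.
#' @return A `glyc_reaction_network`: list with `states` (named list of
#'   oligomers keyed by canonical string), `edges` (tibble `from`, `to`,
#'   `enzyme`, `node`, `carbon`, `rate`), `input` (canonical string),
#'   `truncated`, `clipped` (states whose expansion was suppressed by the
#'   cap) and `terminal` (states with no applicable enzyme at all).
#' @export
build_reaction_network <- function(c, input, size_cap,
                                   max_states = 50000L,
                                   stop_on_truncation = FALSE) {
  stopifnot(inherits(c, "glyc_compartment"), inherits(input, "glyc_oligomer"))
  if (size_cap < oligomer_size(input)) {
    stop("size_cap must be at least the input size", call. = FALSE)
  }
  states <- new.env(parent = emptyenv())
  key0 <- serialize_canonical(input)
  assign(key0, input, envir = states)
  from <- character(0); to <- character(0); enz <- character(0)
  e_node <- integer(0); e_carbon <- integer(0); e_rate <- numeric(0)
  terminal <- character(0); clipped <- character(0)
  truncated <- FALSE
  stack <- list(list(key = key0, o = input))
  n_states <- 1L
  while (length(stack) > 0L) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    o <- cur$o
    any_site <- FALSE
    over_cap <- FALSE
    for (e in c$enzymes) {
      if (e$concentration == 0) next # present but inactive
      sites <- match_nodes(e, o)
      if (length(sites) == 0L) next
      any_site <- TRUE
      if (oligomer_size(o) >= size_cap) {
        over_cap <- TRUE
        next
      }
      for (nd in sites) {
        child <- add_monomer(o, node = nd, carbon = e$acceptor_carbon,
                             donor = e$donor_type,
                             donor_carbon = e$donor_carbon)
        ckey <- serialize_canonical(child)
        from <- c(from, cur$key); to <- c(to, ckey); enz <- c(enz, e$name)
        e_node <- c(e_node, nd); e_carbon <- c(e_carbon, e$acceptor_carbon)
        e_rate <- c(e_rate, e$concentration)
        if (!exists(ckey, envir = states, inherits = FALSE)) {
          assign(ckey, child, envir = states)
          n_states <- n_states + 1L
          if (n_states > max_states) {
            stop("reaction network exceeds max_states (", max_states, ")",
                 call. = FALSE)
          }
          stack[[length(stack) + 1L]] <- list(key = ckey, o = child)
        }
      }
    }
    if (!any_site) terminal <- c(terminal, cur$key)
    if (over_cap) {
      clipped <- c(clipped, cur$key)
      truncated <- TRUE
      if (stop_on_truncation) break
    }
  }
  keys <- ls(envir = states, sorted = FALSE)
  structure(
    list(
      states = rlang::set_names(lapply(keys, get, envir = states), keys),
      edges = tibble::tibble(from = from, to = to, enzyme = enz,
                             node = e_node, carbon = e_carbon, rate = e_rate),
      input = key0,
      truncated = truncated,
      clipped = unique(clipped),
      terminal = unique(terminal)
    ),
    class = "glyc_reaction_network"
  )
}

#' @export
print.glyc_reaction_network <- function(x, ...) {
  cat("<glyc_reaction_network> ", length(x$states), " states, ",
      nrow(x$edges), " reactions, ", length(x$terminal), " terminal",
      if (x$truncated) ", TRUNCATED at size cap" else "", "\n", sep = "")
  invisible(x)
}

#' @method tidy glyc_reaction_network
#' @export
tidy.glyc_reaction_network <- function(x, ...) x$edges

#' @method glance glyc_reaction_network
#' @export
glance.glyc_reaction_network <- function(x, ...) {
  tibble::tibble(
    n_states = length(x$states), n_reactions = nrow(x$edges),
    n_terminal = length(x$terminal), truncated = x$truncated,
    input = x$input
  )
}

#' Detect divergent forks in a finite reaction network
#'
#' A divergent reaction is a fork in the reaction network that never
#' reconverges: from one state, two different additions lead to subgraphs
#' with no common descendant, so the molecule's fate is decided by the random
#' order of enzyme encounters. Forks onto distinct free carbons typically
#' reconverge (both additions happen eventually in either order); forks from
#' enzymes competing for the same carbon cannot.
#'
#' If the network is truncated, descendants beyond the size cap are unknown
#' and the result is flagged approximate (`attr(, "approximate")`).
#'
#' @param net A [build_reaction_network()] result.
#' @return A tibble with columns `state`, `child_a`, `child_b` listing
#'   non-reconverging fork pairs (each unordered pair once).
#' @export
detect_divergence <- function(net) {
  keys <- names(net$states)
  idx <- rlang::set_names(seq_along(keys), keys)
  # descendants (as index sets) via reverse topological order; the network is
  # a DAG graded by oligomer size
  sizes <- vapply(net$states, oligomer_size, integer(1))
  ord <- order(sizes, decreasing = TRUE)
  desc <- vector("list", length(keys))
  kids <- split(idx[net$edges$to], net$edges$from)
  for (i in ord) {
    k <- keys[i]
    ch <- unique(kids[[k]])
    d <- i
    for (c_ in ch) d <- c(d, desc[[c_]])
    desc[[i]] <- unique(d)
  }
  out_state <- character(0); out_a <- character(0); out_b <- character(0)
  for (k in keys[lengths(kids[keys]) > 1L]) {
    ch <- sort(unique(kids[[k]]))
    if (length(ch) < 2L) next
    for (a in seq_along(ch)) {
      for (b in seq_along(ch)) {
        if (b <= a) next
        if (length(intersect(desc[[ch[a]]], desc[[ch[b]]])) == 0L) {
          out_state <- c(out_state, k)
          out_a <- c(out_a, keys[ch[a]])
          out_b <- c(out_b, keys[ch[b]])
        }
      }
    }
  }
  res <- tibble::tibble(state = out_state, child_a = out_a, child_b = out_b)
  attr(res, "approximate") <- net$truncated
  res
}

#' Export a reaction network as DOT
#'
#' @param net A `glyc_reaction_network`.
#' @param path Optional file path; when `NULL` the DOT text is returned.
#' @return DOT source as a character scalar (invisibly if written to file).
#' @export
network_to_dot <- function(net, path = NULL) {
  quote_id <- function(s) paste0('"', gsub('"', '\\"', s, fixed = TRUE), '"')
  lines <- c(
    "digraph reaction_network {",
    "  rankdir=TB;",
    paste0("  ", quote_id(names(net$states)),
           ifelse(names(net$states) %in% net$terminal,
                  " [shape=doublecircle];", " [shape=box];")),
    if (nrow(net$edges) > 0L) {
      paste0("  ", quote_id(net$edges$from), " -> ", quote_id(net$edges$to),
             " [label=", quote_id(net$edges$enzyme), "];")
    },
    "}"
  )
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
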