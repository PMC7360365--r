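#' Is a branch-sensitive enzyme disabled by an unsynthesizable trigger?
#'
#' A branch-sensitive enzyme's required branches form its trigger motif. If
#' no oligomer matching the enzyme's acceptor motif can be grown, within the
#' compartment, from any single monomer of the alphabet, the enzyme can only
#' ever act on branched acceptors imported from upstream: its linkage-network
#' edge is considered inactive and it cannot take part in runaway loops.
#' The search is bounded to oligomers of the motif's size (a motif reachable
#' at all from a bare monomer is reachable within its own size, because
#' growth can stop at any point).
#'
#' @param e A branch-sensitive [enzyme_rule()] with nonempty
#'   `required_branches`; other classes are an error, an empty requirement
#'   returns `FALSE` (never trigger-disabled).
#' @param c The [compartment()] whose enzymes may synthesize the motif
#'   (`e` itself included).
#' @param start_types Monomer types to start from; defaults to the whole
#'   alphabet.
#' @return Logical scalar: `TRUE` iff the motif cannot be synthesized.
#' @export
is_trigger_disabled <- function(e, c, start_types = NULL) {
  stopifnot(inherits(e, "glyc_enzyme"), inherits(c, "glyc_compartment"))
  if (e$class != "branch_sensitive") {
    stop("is_trigger_disabled() applies to branch-sensitive enzymes only",
         call. = FALSE)
  }
  if (length(e$required_branches) == 0L) return(FALSE)
  motif_size <- 1L + sum(vapply(e$required_branches, function(b) {
    oligomer_size(b$pattern)
  }, integer(1)))
  start_types <- start_types %||% names(e$alphabet)
  for (tn in start_types) {
    if (motif_reachable(e, c, tn, motif_size)) return(FALSE)
  }
  TRUE
}

# can an oligomer matching e be grown from a bare monomer of type start_type
# using c's enzymes, within the given oligomer-size bound?
motif_reachable <- function(e, c, start_type, size_bound) {
  start <- oligomer(start_type, e$alphabet)
  seen <- new.env(parent = emptyenv())
  key0 <- serialize_canonical(start)
  assign(key0, TRUE, envir = seen)
  stack <- list(start)
  while (length(stack) > 0L) {
    o <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (length(match_nodes(e, o)) > 0L) return(TRUE)
    if (oligomer_size(o) >= size_bound) next
    for (enz in c$enzymes) {
      if (enz$concentration == 0) next
      for (nd in match_nodes(enz, o)) {
        child <- add_monomer(o, node = nd, carbon = enz$acceptor_carbon,
                             donor = enz$donor_type,
                             donor_carbon = enz$donor_carbon)
        ckey <- serialize_canonical(child)
        if (!exists(ckey, envir = seen, inherits = FALSE)) {
          assign(ckey, TRUE, envir = seen)
          stack[[length(stack) + 1L]] <- child
        }
      }
    }
  }
  FALSE
}

#' Build the linkage network of a compartment
#'
#' The linkage network is a directed multigraph over monomer *types*: one
#' edge per enzyme, from its acceptor type to its donor type, labeled with
#' the carbon pair. It summarizes every order in which monomer types can be
#' linked within the compartment. Branch-sensitive edges whose trigger motif
#' cannot be synthesized in-compartment are marked inactive.
#'
#' @param c A [compartment()].
#' @return A `glyc_linkage_network`: tibble with columns `enzyme`, `from`
#'   (acceptor type), `to` (donor type), `acceptor_carbon`, `donor_carbon`,
#'   `class`, `active`, carrying the compartment as an attribute.
#' @export
build_linkage_network <- function(c) {
  stopifnot(inherits(c, "glyc_compartment"))
  rows <- lapply(c$enzymes, function(e) {
    active <- e$concentration > 0
    if (active && e$class == "branch_sensitive" &&
        length(e$required_branches) > 0L) {
      active <- !is_trigger_disabled(e, c)
    }
    tibble::tibble(
      enzyme = e$name, from = e$acceptor_type, to = e$donor_type,
      acceptor_carbon = e$acceptor_carbon, donor_carbon = e$donor_carbon,
      class = e$class, active = active
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("glyc_linkage_network", class(out))
  attr(out, "compartment") <- c
  out
}

# elementary cycles of a directed multigraph given as an edge tibble with
# columns from/to; returns a list of type-cycles, each a list with `types`
# (the node sequence, first node repeated implicitly) and `edges` (for each
# step, the enzyme names of the parallel edges that realize it)
elementary_type_cycles <- function(edges) {
  if (nrow(edges) == 0L) return(list())
  nodes <- sort(unique(c(edges$from, edges$to)))
  adj <- lapply(rlang::set_names(nodes), function(v) {
    unique(edges$to[edges$from == v])
  })
  cycles <- list()
  # enumerate simple cycles whose lexicographically smallest node comes first
  for (start in nodes) {
    path <- start
    visit <- function(v) {
      for (w in adj[[v]]) {
        if (w == start) {
          cycles[[length(cycles) + 1L]] <<- path
        } else if (!(w %in% path) && w > start) {
          path <<- c(path, w)
          visit(w)
          path <<- path[-length(path)]
        }
      }
    }
    visit(start)
  }
  lapply(cycles, function(cyc) {
    steps <- lapply(seq_along(cyc), function(i) {
      a <- cyc[i]
      b <- cyc[if (i == length(cyc)) 1L else i + 1L]
      edges$enzyme[edges$from == a & edges$to == b]
    })
    list(types = cyc, enzymes = steps)
  })
}

#' Detect runaway reactions via linkage-network loops
#'
#' A runaway reaction is an infinite path in the reaction network, producing
#' oligomers with arbitrarily many tandem repeats. A compartment contains a
#' runaway reaction iff its linkage network, restricted to active edges of
#' non-root-sensitive enzymes, contains a directed loop (root-sensitive
#' enzymes pin their acceptor at a fixed depth and cannot loop).
#'
#' With an `input` oligomer, only loops that are actually reachable from it
#' are returned. Reachability is a fireable-enzyme closure: a bounded
#' reaction probe finds enzymes that can fire starting from the input, then
#' fresh-monomer propagation closes the set (an enzyme fires on a freshly
#' added acceptor iff it is context-free, or branch-sensitive with its motif
#' synthesizable from the bare acceptor monomer). A loop is reachable iff
#' every step can sustain itself on fresh monomers and at least one step
#' enzyme is in the fireable closure.
#'
#' @param c A [compartment()].
#' @param input Optional `glyc_oligomer`; `NULL` gives the compartment-wide
#'   (input-free) answer.
#' @param probe_extra,probe_max_states Bounds of the fireability probe.
#' @return A list of loops, each `list(types =, enzymes =)`; empty if the
#'   reaction network is finite.
#' @export
detect_runaway <- function(c, input = NULL, probe_extra = 8L,
                           probe_max_states = 3000L) {
  lnet <- build_linkage_network(c)
  loopable <- lnet[lnet$active & lnet$class != "root_sensitive", , drop = FALSE]
  # a loop edge must sustain itself on fresh acceptor monomers
  sustain <- vapply(loopable$enzyme, function(nm) {
    e <- c$enzymes[[nm]]
    fresh_fires(e, c)
  }, logical(1))
  loopable <- loopable[sustain, , drop = FALSE]
  cycles <- elementary_type_cycles(loopable)
  if (is.null(input) || length(cycles) == 0L) return(cycles)
  fire <- fireable_closure(c, input, probe_extra, probe_max_states)
  keep <- vapply(cycles, function(cyc) {
    any(unlist(cyc$enzymes) %in% fire)
  }, logical(1))
  cycles[keep]
}

# can e fire on a freshly added (bare) monomer of its own acceptor type,
# given in-compartment growth of that monomer's branches?
fresh_fires <- function(e, c) {
  switch(e$class,
    context_free = TRUE,
    branch_sensitive = {
      if (length(e$required_branches) == 0L) {
        # only forbidden constraints: a bare monomer satisfies "lacking"
        # constraints trivially
        TRUE
      } else {
        motif_size <- 1L + sum(vapply(e$required_branches, function(b) {
          oligomer_size(b$pattern)
        }, integer(1)))
        motif_reachable(e, c, e$acceptor_type, motif_size)
      }
    },
    root_sensitive = FALSE
  )
}

# names of enzymes that can ever fire starting from `input`: a bounded
# reaction-network probe plus fresh-monomer propagation
fireable_closure <- function(c, input, probe_extra = 8L,
                             probe_max_states = 3000L) {
  fired <- character(0)
  seen <- new.env(parent = emptyenv())
  key0 <- serialize_canonical(input)
  assign(key0, TRUE, envir = seen)
  stack <- list(input)
  n_states <- 1L
  cap <- oligomer_size(input) + probe_extra
  while (length(stack) > 0L && n_states <= probe_max_states) {
    o <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (e in c$enzymes) {
      if (e$concentration == 0) next
      sites <- match_nodes(e, o)
      if (length(sites) > 0L) fired <- union(fired, e$name)
      if (oligomer_size(o) >= cap) next
      for (nd in sites) {
        child <- add_monomer(o, node = nd, carbon = e$acceptor_carbon,
                             donor = e$donor_type,
                             donor_carbon = e$donor_carbon)
        ckey <- serialize_canonical(child)
        if (!exists(ckey, envir = seen, inherits = FALSE)) {
          assign(ckey, TRUE, envir = seen)
          n_states <- n_states + 1L
          stack[[length(stack) + 1L]] <- child
        }
      }
    }
  }
  # fresh propagation: enzymes firing on monomer types freshly addable by
  # already-fireable enzymes
  repeat {
    fresh_types <- unique(vapply(c$enzymes[fired], function(e) e$donor_type,
                                 character(1)))
    new_fired <- vapply(c$enzymes, function(e) {
      !(e$name %in% fired) && e$acceptor_type %in% fresh_types &&
        fresh_fires(e, c)
    }, logical(1))
    if (!any(new_fired)) break
    fired <- union(fired, names(c$enzymes)[new_fired])
  }
  fired
}

#' Export a linkage network as DOT
#'
#' @param lnet A [build_linkage_network()] result.
#' @param path Optional file path.
#' @return DOT source (invisibly if written).
#' @export
linkage_to_dot <- function(lnet, path = NULL) {
  lines <- c(
    "digraph linkage_network {",
    paste0("  \"", unique(c(lnet$from, lnet$to)), "\";"),
    paste0("  \"", lnet$from, "\" -> \"", lnet$to, "\" [label=\"",
           lnet$enzyme, " (", lnet$acceptor_carbon, "-", lnet$donor_carbon,
           ")\"", ifelse(lnet$active, "", ", style=dashed"), "];"),
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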