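#' Define a glycosyltransferase rule
#'
#' One GTase enzyme catalyzes a specific glycosidic bond: it attaches a free
#' monomer of `donor_type` (through `donor_carbon`) to `acceptor_carbon` of
#' an acceptor monomer of `acceptor_type`. How much context the enzyme reads
#' around the acceptor monomer is its promiscuity class:
#'
#' * `context_free` — the acceptor is the bare monomer type; maximally
#'   promiscuous.
#' * `branch_sensitive` — the acceptor monomer must carry (`required_branches`)
#'   and/or lack (`forbidden_branches`) specific branch subtrees, read to
#'   arbitrary depth (ideal branch sensitivity: a required pattern must match
#'   the full branch, not a prefix of it).
#' * `root_sensitive` — the acceptor monomer must sit on a specific chain of
#'   linkages running all the way down to the root (ideal root sensitivity);
#'   such enzymes can distinguish the position of every monomer in the tree.
#'
#' Donor-substrate (nucleotide sugar) availability is assumed unlimited; the
#' single kinetic parameter is `concentration`, the propensity with which
#' each matching site fires per unit time.
#'
#' @param name Enzyme name (unique within a library).
#' @param donor_type,acceptor_type Monomer type names from `alphabet`.
#' @param acceptor_carbon Carbon on the acceptor where the new bond forms.
#' @param donor_carbon Carbon of the donor used in the bond; defaults to the
#'   donor type's declared donor carbon.
#' @param class One of `"context_free"`, `"branch_sensitive"`,
#'   `"root_sensitive"` (abbreviations `"cf"`, `"bs"`, `"rs"` accepted).
#' @param required_branches For branch-sensitive rules: a list of branch
#'   patterns, each a list `list(carbon =, pattern =, dc =)` where `pattern`
#'   is a `glyc_oligomer` (the exact branch subtree) or a string in the
#'   oligomer grammar, and `dc` the donor carbon of the branch bond
#'   (defaults to the pattern root's donor carbon). A string shorthand
#'   `"Fuc(2-1)"` is accepted for a whole entry.
#' @param forbidden_branches Same layout; `pattern = "*"` is a wildcard
#'   meaning the carbon must be empty. Shorthand strings `"*2"` (wildcard at
#'   carbon 2) and `"Fuc(2-1)"` are accepted.
#' @param root_chain For root-sensitive rules: the required chain from the
#'   acceptor down to the root, as a string like `"(3-1)Gal(3-1)GlcNAc"`
#'   (read: the acceptor hangs from carbon 3 of a Gal via donor carbon 1,
#'   and that Gal from carbon 3 of the GlcNAc root) or a list of
#'   `list(ac =, dc =, type =)` entries. An empty chain means the acceptor
#'   is the root itself.
#' @param concentration Positive propensity scale; default 1.
#' @param alphabet A [monomer_alphabet()].
#' @return An object of class `glyc_enzyme`.
#' @examples
#' ab <- monomer_alphabet(c("GlcNAc", "Gal", "Fuc"))
#' fut2 <- enzyme_rule("Fut2", donor_type = "Fuc", acceptor_type = "Gal",
#'                     acceptor_carbon = 2, class = "rs",
#'                     root_chain = "(3-1)GlcNAc", alphabet = ab)
#' gtb <- enzyme_rule("GTB", donor_type = "Gal", acceptor_type = "Gal",
#'                    acceptor_carbon = 3, class = "bs",
#'                    required_branches = "Fuc(2-1)", alphabet = ab)
#' @export
enzyme_rule <- function(name, donor_type, acceptor_type, acceptor_carbon,
                        donor_carbon = NULL,
                        class = c("context_free", "branch_sensitive",
                                  "root_sensitive", "cf", "bs", "rs"),
                        required_branches = list(),
                        forbidden_branches = list(),
                        root_chain = list(),
                        concentration = 1,
                        alphabet) {
  stopifnot(inherits(alphabet, "glyc_alphabet"))
  class <- match.arg(class)
  abbr <- c(cf = "context_free", bs = "branch_sensitive", rs = "root_sensitive")
  if (class %in% names(abbr)) class <- abbr[[class]]
  for (tn in c(donor_type, acceptor_type)) {
    if (!tn %in% names(alphabet)) stop("unknown monomer type: ", tn, call. = FALSE)
  }
  acceptor_carbon <- as.integer(acceptor_carbon)
  if (!acceptor_carbon %in% alphabet[[acceptor_type]]$acceptor_carbons) {
    stop("carbon ", acceptor_carbon, " is not an acceptor carbon of ",
         acceptor_type, call. = FALSE)
  }
  donor_carbon <- as.integer(donor_carbon %||% alphabet[[donor_type]]$donor_carbon)
  if (concentration < 0) {
    stop("concentration must be nonnegative", call. = FALSE)
  }

  required <- normalize_branch_specs(required_branches, acceptor_type, alphabet)
  forbidden <- normalize_branch_specs(forbidden_branches, acceptor_type, alphabet,
                                      allow_wildcard = TRUE)
  chain <- normalize_root_chain(root_chain, alphabet)

  if (class != "branch_sensitive" && (length(required) || length(forbidden))) {
    stop("branch constraints are only meaningful for branch-sensitive rules",
         call. = FALSE)
  }
  if (class != "root_sensitive" && length(chain)) {
    stop("a root chain is only meaningful for root-sensitive rules",
         call. = FALSE)
  }
  req_carbons <- vapply(required, function(b) b$carbon, integer(1))
  forb_carbons <- vapply(forbidden, function(b) b$carbon, integer(1))
  if (length(intersect(req_carbons, forb_carbons)) > 0L) {
    stop("required and forbidden branch carbons must be disjoint", call. = FALSE)
  }
  if (anyDuplicated(req_carbons) || anyDuplicated(forb_carbons)) {
    stop("at most one branch constraint per carbon", call. = FALSE)
  }

  structure(
    list(name = name, class = class,
         donor_type = donor_type, donor_carbon = donor_carbon,
         acceptor_type = acceptor_type, acceptor_carbon = acceptor_carbon,
         required_branches = required, forbidden_branches = forbidden,
         root_chain = chain, concentration = as.numeric(concentration),
         alphabet = alphabet),
    class = "glyc_enzyme"
  )
}

# branch specs -> list of list(carbon, dc, pattern = glyc_oligomer or "*")
normalize_branch_specs <- function(specs, acceptor_type, alphabet,
                                   allow_wildcard = FALSE) {
  if (length(specs) == 0L) return(list())
  if (is.character(specs)) specs <- as.list(specs)
  if (!is.null(specs$carbon)) specs <- list(specs) # single bare entry
  lapply(specs, function(s) {
    if (is.character(s) && length(s) == 1L) {
      if (grepl("^\\*", s)) {
        if (!allow_wildcard) stop("wildcard only allowed in forbidden branches",
                                  call. = FALSE)
        carbon <- as.integer(sub("^\\*", "", s))
        s <- list(carbon = carbon, pattern = "*")
      } else {
        # "Subtree(ac-dc)" shorthand
        m <- regmatches(s, regexec("^(.*)\\((\\d+)-(\\d+)\\)$", s))[[1]]
        if (length(m) != 4L) {
          stop("cannot parse branch shorthand: ", s, call. = FALSE)
        }
        s <- list(carbon = as.integer(m[3]), dc = as.integer(m[4]),
                  pattern = m[2])
      }
    }
    carbon <- as.integer(s$carbon)
    if (!carbon %in% alphabet[[acceptor_type]]$acceptor_carbons) {
      stop("branch carbon ", carbon, " is not an acceptor carbon of ",
           acceptor_type, call. = FALSE)
    }
    pat <- s$pattern
    if (identical(pat, "*")) {
      if (!allow_wildcard) stop("wildcard only allowed in forbidden branches",
                                call. = FALSE)
      return(list(carbon = carbon, dc = NA_integer_, pattern = "*"))
    }
    if (is.character(pat)) pat <- parse_oligomer(pat, alphabet)
    stopifnot(inherits(pat, "glyc_oligomer"))
    dc <- as.integer(s$dc %||% alphabet[[pat$type[1L]]]$donor_carbon)
    list(carbon = carbon, dc = dc, pattern = pat)
  })
}

# root chain -> list of list(ac, dc, type), acceptor-side first, root last
normalize_root_chain <- function(chain, alphabet) {
  if (length(chain) == 0L) return(list())
  if (is.character(chain) && length(chain) == 1L) {
    s <- chain
    out <- list()
    while (nchar(s) > 0L) {
      m <- regmatches(s, regexec("^\\((\\d+)-(\\d+)\\)([A-Za-z][A-Za-z0-9]*)", s))[[1]]
      if (length(m) != 4L) stop("cannot parse root chain: ", chain, call. = FALSE)
      out <- c(out, list(list(ac = as.integer(m[2]), dc = as.integer(m[3]),
                              type = m[4])))
      s <- substr(s, nchar(m[1]) + 1L, nchar(s))
    }
    chain <- out
  }
  lapply(chain, function(e) {
    if (!e$type %in% names(alphabet)) {
      stop("unknown monomer type in root chain: ", e$type, call. = FALSE)
    }
    if (!as.integer(e$ac) %in% alphabet[[e$type]]$acceptor_carbons) {
      stop("root chain uses carbon ", e$ac, " which is not an acceptor carbon of ",
           e$type, call. = FALSE)
    }
    list(ac = as.integer(e$ac), dc = as.integer(e$dc), type = e$type)
  })
}

#' @export
format.glyc_enzyme <- function(x, ...) {
  cls <- c(context_free = "CF", branch_sensitive = "BS",
           root_sensitive = "RS")[[x$class]]
  extras <- character(0)
  if (length(x$required_branches)) {
    extras <- c(extras, paste0("requires ", paste(vapply(
      x$required_branches, branch_spec_string, character(1)), collapse = "+")))
  }
  if (length(x$forbidden_branches)) {
    extras <- c(extras, paste0("lacks ", paste(vapply(
      x$forbidden_branches, branch_spec_string, character(1)), collapse = "+")))
  }
  if (length(x$root_chain)) {
    extras <- c(extras, paste0("root chain ", root_chain_string(x$root_chain)))
  }
  sprintf("%s [%s] %s(%d) -> %s@%d%s", x$name, cls, x$donor_type,
          x$donor_carbon, x$acceptor_type, x$acceptor_carbon,
          if (length(extras)) paste0(" {", paste(extras, collapse = "; "), "}")
          else "")
}

branch_spec_string <- function(b) {
  if (identical(b$pattern, "*")) return(paste0("*", b$carbon))
  paste0(subtree_string(b$pattern, 1L), "(", b$carbon, "-", b$dc, ")")
}

root_chain_string <- function(chain) {
  paste0(vapply(chain, function(e) paste0("(", e$ac, "-", e$dc, ")", e$type),
                character(1)), collapse = "")
}

#' @export
print.glyc_enzyme <- function(x, ...) {
  cat("<glyc_enzyme> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Find every site where an enzyme can act
#'
#' Scans the oligomer (depth-first, canonical child order) for free sites
#' matching the enzyme's acceptor-substrate: the node has the acceptor type,
#' the acceptor carbon is unoccupied, and the class constraints hold
#' (required branch subtrees present as exact full-subtree matches,
#' forbidden branches absent, or the full path to the root equal to the
#' required root chain).
#'
#' @param e A [enzyme_rule()].
#' @param o A `glyc_oligomer`.
#' @return A tibble of sites as in [free_sites()]; zero rows if the enzyme
#'   cannot act.
#' @export
match_sites <- function(e, o) {
  nodes <- match_nodes(e, o)
  tibble::tibble(
    node = nodes, carbon = rep.int(e$acceptor_carbon, length(nodes)),
    type = o$type[nodes],
    path = lapply(nodes, function(i) node_path(o, i))
  )
}

# bare integer vector of matching nodes in depth-first canonical order;
# the fast path used by network expansion and simulation
match_nodes <- function(e, o) {
  cand <- which(o$type == e$acceptor_type)
  if (length(cand) == 0L) return(integer(0))
  cand <- cand[vapply(cand, function(i) node_matches(e, o, i), logical(1))]
  if (length(cand) > 1L) {
    ord <- dfs_order(o)
    cand <- cand[order(match(cand, ord))]
  }
  cand
}

# does enzyme e match node i of o (including carbon freedom)?
node_matches <- function(e, o, i) {
  if (o$type[i] != e$acceptor_type) return(FALSE)
  if (e$acceptor_carbon %in% occupied_carbons(o, i)) return(FALSE)
  switch(e$class,
    context_free = TRUE,
    branch_sensitive = branch_constraints_hold(e, o, i),
    root_sensitive = root_chain_holds(e, o, i)
  )
}

branch_constraints_hold <- function(e, o, i) {
  ch <- children_of(o, i)
  ch_ac <- o$ac[ch]
  for (b in e$required_branches) {
    pos <- ch[ch_ac == b$carbon]
    if (length(pos) != 1L) return(FALSE)
    if (o$dc[pos] != b$dc) return(FALSE)
    if (subtree_string(o, pos) != subtree_string(b$pattern, 1L)) return(FALSE)
  }
  for (b in e$forbidden_branches) {
    pos <- ch[ch_ac == b$carbon]
    if (identical(b$pattern, "*")) {
      if (length(pos) > 0L) return(FALSE)
    } else if (length(pos) == 1L &&
               o$dc[pos] == b$dc &&
               subtree_string(o, pos) == subtree_string(b$pattern, 1L)) {
      return(FALSE)
    }
  }
  TRUE
}

root_chain_holds <- function(e, o, i) {
  for (entry in e$root_chain) {
    p <- o$parent[i]
    if (is.na(p)) return(FALSE)
    if (o$ac[i] != entry$ac || o$dc[i] != entry$dc) return(FALSE)
    if (o$type[p] != entry$type) return(FALSE)
    i <- p
  }
  is.na(o$parent[i]) # chain must be anchored at the root
}

#' Apply an enzyme at a matched site
#'
#' Attaches the enzyme's donor monomer at the given site, which must be one
#' of [match_sites()] for this enzyme.
#'
#' @param e A [enzyme_rule()].
#' @param o A `glyc_oligomer`.
#' @param node Node index of the acceptor (a row of `match_sites(e, o)`).
#' @return The grown `glyc_oligomer`.
#' @export
apply_enzyme <- function(e, o, node) {
  if (!node_matches(e, o, node)) {
    stop("enzyme ", e$name, " does not match node ", node, call. = FALSE)
  }
  add_monomer(o, node = node, carbon = e$acceptor_carbon, donor = e$donor_type,
              donor_carbon = e$donor_carbon)
}

#' Construct the ideal enzyme of a class realizing one growth step
#'
#' Given a parent oligomer, a free site on it and a donor, builds the
#' class-`cls` enzyme whose acceptor-substrate is read off the parent
#' oligomer: for `root_sensitive`, the acceptor node's actual path to the
#' root; for `branch_sensitive`, the acceptor node's current branch subtrees
#' as required branches (optionally also forbidding every other carbon, via
#' `forbid_absent`); for `context_free`, no constraints. The returned enzyme
#' always matches the given site on the parent oligomer.
#'
#' @param cls Promiscuity class (full name or `"cf"`/`"bs"`/`"rs"`).
#' @param parent_oligomer A `glyc_oligomer`.
#' @param node,carbon The free site the enzyme should realize.
#' @param donor,donor_carbon The monomer to attach.
#' @param forbid_absent For branch-sensitive rules: also forbid (wildcard)
#'   every currently empty acceptor carbon other than the target carbon.
#'   Default `FALSE` (permissive: the rule only requires the branches that
#'   are present).
#' @param name Optional enzyme name; a descriptive one is generated.
#' @param concentration Propensity, default 1.
#' @return A `glyc_enzyme`.
#' @export
make_ideal_enzyme <- function(cls, parent_oligomer, node, carbon, donor,
                              donor_carbon = NULL, forbid_absent = FALSE,
                              name = NULL, concentration = 1) {
  o <- parent_oligomer
  cls <- match.arg(cls, c("context_free", "branch_sensitive", "root_sensitive",
                          "cf", "bs", "rs"))
  abbr <- c(cf = "context_free", bs = "branch_sensitive", rs = "root_sensitive")
  if (cls %in% names(abbr)) cls <- abbr[[cls]]
  acceptor_type <- o$type[node]
  if (carbon %in% occupied_carbons(o, node)) {
    stop("site is occupied", call. = FALSE)
  }
  required <- list(); forbidden <- list(); chain <- list()
  if (cls == "branch_sensitive") {
    for (c_ in children_of(o, node)) {
      required <- c(required, list(list(carbon = o$ac[c_], dc = o$dc[c_],
                                        pattern = extract_subtree(o, c_))))
    }
    if (forbid_absent) {
      free_other <- setdiff(o$alphabet[[acceptor_type]]$acceptor_carbons,
                            c(occupied_carbons(o, node), carbon))
      forbidden <- lapply(free_other, function(k) {
        list(carbon = k, pattern = "*")
      })
    }
  } else if (cls == "root_sensitive") {
    i <- node
    while (!is.na(o$parent[i])) {
      chain <- c(chain, list(list(ac = o$ac[i], dc = o$dc[i],
                                  type = o$type[o$parent[i]])))
      i <- o$parent[i]
    }
  }
  name <- name %||% sprintf("%s_%s%d_%s",
                            c(context_free = "cf", branch_sensitive = "bs",
                              root_sensitive = "rs")[[cls]],
                            acceptor_type, carbon, donor)
  enzyme_rule(name, donor_type = donor, acceptor_type = acceptor_type,
              acceptor_carbon = carbon, donor_carbon = donor_carbon,
              class = cls, required_branches = required,
              forbidden_branches = forbidden, root_chain = chain,
              concentration = concentration, alphabet = o$alphabet)
}

# identity key of an enzyme's behavior (used for dedup in planners)
enzyme_key <- function(e) {
  paste(e$class, e$acceptor_type, e$acceptor_carbon, e$donor_type,
        e$donor_carbon,
        paste(vapply(e$required_branches, branch_spec_string, character(1)),
              collapse = ","),
        paste(vapply(e$forbidden_branches, branch_spec_string, character(1)),
              collapse = ","),
        root_chain_string(e$root_chain),
        sep = "|")
}

#' Read or write an enzyme library as YAML
#'
#' Each entry holds name, class, donor/acceptor types and carbons,
#' constraint patterns in the oligomer grammar shorthand (see
#' [enzyme_rule()]) and concentration.
#'
#' @param path File path.
#' @param library A list of `glyc_enzyme`s.
#' @param alphabet A [monomer_alphabet()].
#' @return `read_enzyme_library()` returns a list of `glyc_enzyme`s.
#' @export
read_enzyme_library <- function(path, alphabet) {
  entries <- yaml::read_yaml(path)
  lapply(entries, function(en) {
    enzyme_rule(
      name = en$name, donor_type = en$donor_type,
      acceptor_type = en$acceptor_type,
      acceptor_carbon = en$acceptor_carbon,
      donor_carbon = en$donor_carbon,
      class = en$class,
      required_branches = en$required_branches %||% list(),
      forbidden_branches = en$forbidden_branches %||% list(),
      root_chain = en$root_chain %||% list(),
      concentration = en$concentration %||% 1,
      alphabet = alphabet
    )
  })
}

#' @rdname read_enzyme_library
#' @export
write_enzyme_library <- function(library, path) {
  entries <- lapply(library, function(e) {
    out <- list(
      name = e$name, class = e$class, donor_type = e$donor_type,
      donor_carbon = e$donor_carbon, acceptor_type = e$acceptor_type,
      acceptor_carbon = e$acceptor_carbon, concentration = e$concentration
    )
    if (length(e$required_branches)) {
      out$required_branches <- vapply(e$required_branches, branch_spec_string,
                                      character(1))
    }
    if (length(e$forbidden_branches)) {
      out$forbidden_branches <- vapply(e$forbidden_branches, branch_spec_string,
                                       character(1))
    }
    if (length(e$root_chain)) out$root_chain <- root_chain_string(e$root_chain)
    out
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}
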