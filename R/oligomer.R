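#' Branched glycan oligomers as rooted trees
#'
#' An oligomer is a rooted tree of typed monomers. Each non-root monomer is
#' attached to its parent at one of the parent's acceptor carbons, through
#' one of its own carbons (the donor carbon of the bond). A carbon, once
#' linked, is occupied: at most one branch per acceptor carbon. Oligomers
#' only grow (additions are irreversible); they are never pruned.
#'
#' Internally an oligomer is a struct-of-arrays: parallel vectors `type`,
#' `parent`, `ac` (carbon on the parent) and `dc` (carbon on the child),
#' with node 1 the root. This keeps site scanning and monomer addition cheap.
#'
#' @param type_name Name of the root monomer type.
#' @param alphabet A [monomer_alphabet()].
#' @return A `glyc_oligomer`.
#' @examples
#' ab <- monomer_alphabet(c("GlcNAc", "Gal", "Fuc"))
#' o <- oligomer("GlcNAc", ab)
#' oligomer_size(o)
#' @export
oligomer <- function(type_name, alphabet) {
  stopifnot(inherits(alphabet, "glyc_alphabet"))
  if (!type_name %in% names(alphabet)) {
    stop("unknown monomer type: ", type_name, call. = FALSE)
  }
  new_oligomer(type = type_name, parent = NA_integer_, ac = NA_integer_,
               dc = NA_integer_, alphabet = alphabet)
}

new_oligomer <- function(type, parent, ac, dc, alphabet) {
  structure(
    list(type = as.character(type), parent = as.integer(parent),
         ac = as.integer(ac), dc = as.integer(dc), alphabet = alphabet),
    class = "glyc_oligomer"
  )
}

#' @rdname oligomer
#' @param o,a,b Oligomers.
#' @export
oligomer_size <- function(o) length(o$type)

#' @export
format.glyc_oligomer <- function(x, ...) serialize_canonical(x)

#' @export
print.glyc_oligomer <- function(x, ...) {
  cat("<glyc_oligomer> ", serialize_canonical(x), "  (", oligomer_size(x),
      " monomers)\n", sep = "")
  invisible(x)
}

#' @export
as.character.glyc_oligomer <- function(x, ...) serialize_canonical(x)

# children of node i, ordered by ascending acceptor carbon
children_of <- function(o, i) {
  ch <- which(!is.na(o$parent) & o$parent == i)
  if (length(ch) > 1L) ch <- ch[order(o$ac[ch])]
  ch
}

# carbons of node i already carrying a branch
occupied_carbons <- function(o, i) {
  o$ac[!is.na(o$parent) & o$parent == i]
}

#' Validate the structural invariants of an oligomer
#'
#' Checks the tree property (single root, no cycles), carbon validity of
#' every linkage against the alphabet, and the one-branch-per-carbon rule.
#'
#' @param o A `glyc_oligomer`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_oligomer <- function(o) {
  stopifnot(inherits(o, "glyc_oligomer"))
  n <- oligomer_size(o)
  if (n < 1L) stop("oligomer must contain at least one monomer", call. = FALSE)
  if (sum(is.na(o$parent)) != 1L || !is.na(o$parent[1L])) {
    stop("oligomer must have exactly one root at node 1", call. = FALSE)
  }
  for (i in seq_len(n)) {
    if (!o$type[i] %in% names(o$alphabet)) {
      stop("unknown monomer type: ", o$type[i], call. = FALSE)
    }
    if (i > 1L) {
      p <- o$parent[i]
      if (is.na(p) || p < 1L || p > n) {
        stop("invalid parent index at node ", i, call. = FALSE)
      }
      ptype <- o$alphabet[[o$type[p]]]
      if (!o$ac[i] %in% ptype$acceptor_carbons) {
        stop("carbon ", o$ac[i], " is not an acceptor carbon of ", ptype$name,
             call. = FALSE)
      }
      if (is.na(o$dc[i]) || o$dc[i] <= 0L) {
        stop("donor carbon must be positive", call. = FALSE)
      }
    }
  }
  for (i in seq_len(n)) {
    occ <- occupied_carbons(o, i)
    if (anyDuplicated(occ)) {
      stop("duplicate branch on one acceptor carbon of node ", i, call. = FALSE)
    }
    if (!reachable_root(o, i)) stop("cycle detected in oligomer", call. = FALSE)
  }
  invisible(TRUE)
}

reachable_root <- function(o, i) {
  seen <- integer(0)
  while (!is.na(o$parent[i])) {
    if (i %in% seen) return(FALSE)
    seen <- c(seen, i)
    i <- o$parent[i]
  }
  i == 1L
}

# canonical subtree strings of every node, with every child bracketed.
# Computed bottom-up (nodes are stored parent-before-child), so arbitrarily
# deep oligomers do not recurse.
node_strings <- function(o) {
  n <- length(o$type)
  res <- character(n)
  kids <- vector("list", n)
  if (n > 1L) {
    for (j in 2:n) {
      p <- o$parent[j]
      kids[[p]] <- c(kids[[p]], j)
    }
  }
  for (i in n:1) {
    ch <- kids[[i]]
    if (length(ch) == 0L) {
      res[i] <- o$type[i]
    } else {
      ch <- ch[order(o$ac[ch])]
      res[i] <- paste0(
        paste0("[", res[ch], "(", o$ac[ch], "-", o$dc[ch], ")]",
               collapse = ""),
        o$type[i]
      )
    }
  }
  res
}

# canonical subtree string of node i (every child bracketed); used for
# subtree pattern comparison and inside serialize_canonical()
subtree_string <- function(o, i) {
  node_strings(o)[i]
}

#' Serialize an oligomer to its canonical string
#'
#' The canonical grammar writes trees child-first with the root last
#' (suffix-root form). Branches are emitted in ascending acceptor-carbon
#' order as bracketed `[Child(ac-dc)]` groups; the root's lowest-carbon
#' child is written unbracketed, giving chain style `Child(ac-dc)Root` at
#' the top (an unbracketed segment always binds to the next node to its
#' right, so the form is unambiguous). Two structurally equal oligomers
#' always serialize to the same string, so the canonical string doubles as
#' an identity key.
#'
#' @param o A `glyc_oligomer`.
#' @return A single string, e.g. `"[Fuc(2-1)][Gal(3-1)]Gal(3-1)GlcNAc"` for
#'   the blood-group B antigen.
#' @export
serialize_canonical <- function(o) {
  ch <- children_of(o, 1L)
  if (length(ch) == 0L) return(o$type[1L])
  strs <- node_strings(o)
  first <- ch[1L]
  rest <- ch[-1L]
  brackets <- if (length(rest) > 0L) {
    paste0("[", strs[rest], "(", o$ac[rest], "-", o$dc[rest], ")]",
           collapse = "")
  } else {
    ""
  }
  paste0(strs[first], "(", o$ac[first], "-", o$dc[first], ")", brackets,
         o$type[1L])
}

#' Test two oligomers for structural equality
#'
#' Equality of rooted trees up to child order; implemented as equality of
#' canonical strings.
#'
#' @param a,b Oligomers.
#' @return Logical scalar.
#' @export
oligomer_equal <- function(a, b) {
  serialize_canonical(a) == serialize_canonical(b)
}

#' Parse an oligomer from its text form
#'
#' Accepts the canonical grammar and its lenient chain variants: a node is
#' written as zero or more bracketed branches `[Subtree(ac-dc)]` followed by
#' its type name; unbracketed `Child(ac-dc)` segments attach to the next
#' node to the right, so `Gal(3-1)GlcNAc` is a two-monomer chain and
#' `Gal(3-1)[Fuc(2-1)]Gal(3-1)GlcNAc` equals the canonical
#' `[Fuc(2-1)][Gal(3-1)]Gal(3-1)GlcNAc`. Whitespace is forbidden.
#'
#' @param text Oligomer string.
#' @param alphabet A [monomer_alphabet()]; all type names in `text` must be
#'   present.
#' @return A `glyc_oligomer`.
#' @examples
#' ab <- monomer_alphabet(c("GlcNAc", "Gal", "Fuc"))
#' parse_oligomer("[Fuc(2-1)][Gal(3-1)]Gal(3-1)GlcNAc", ab)
#' @export
parse_oligomer <- function(text, alphabet) {
  stopifnot(is.character(text), length(text) == 1L,
            inherits(alphabet, "glyc_alphabet"))
  if (grepl("\\s", text)) {
    stop("whitespace is not allowed in oligomer strings", call. = FALSE)
  }
  chars <- strsplit(text, "")[[1]]
  pos <- 1L
  n <- length(chars)

  peek <- function() if (pos <= n) chars[pos] else ""
  fail <- function(msg) {
    stop("parse error at position ", pos, ": ", msg, call. = FALSE)
  }
  expect <- function(ch) {
    if (peek() != ch) fail(paste0("expected '", ch, "'"))
    pos <<- pos + 1L
  }
  parse_int <- function() {
    start <- pos
    while (pos <= n && grepl("[0-9]", chars[pos])) pos <<- pos + 1L
    if (pos == start) fail("expected an integer carbon number")
    as.integer(paste0(chars[start:(pos - 1L)], collapse = ""))
  }
  parse_name <- function() {
    start <- pos
    if (pos > n || !grepl("[A-Za-z]", chars[pos])) fail("expected a type name")
    pos <<- pos + 1L
    while (pos <= n && grepl("[A-Za-z0-9]", chars[pos])) pos <<- pos + 1L
    paste0(chars[start:(pos - 1L)], collapse = "")
  }
  parse_linkage <- function() {
    expect("(")
    a <- parse_int()
    expect("-")
    d <- parse_int()
    expect(")")
    c(a, d)
  }
  attach_child <- function(node, child, ac, dc) {
    ptype <- alphabet[[node$type]]
    if (!ac %in% ptype$acceptor_carbons) {
      fail(paste0("carbon ", ac, " is not an acceptor carbon of ", node$type))
    }
    if (any(vapply(node$children, function(x) x$ac, integer(1)) == ac)) {
      fail(paste0("duplicate branch at carbon ", ac, " of ", node$type))
    }
    if (dc <= 0) fail("donor carbon must be positive")
    node$children <- c(node$children, list(list(ac = ac, dc = dc, node = child)))
    node
  }
  # parse a sequence of units; at depth > 0 the sequence ends with a linked
  # unit followed by ']' and returns the pending (node, ac, dc) attachment
  parse_seq <- function(depth) {
    pending <- NULL
    repeat {
      if (depth > 0L && peek() == "]") {
        if (is.null(pending)) fail("empty bracket")
        pos <<- pos + 1L
        return(pending)
      }
      branches <- list()
      while (peek() == "[") {
        pos <<- pos + 1L
        branches <- c(branches, list(parse_seq(depth + 1L)))
      }
      nm <- parse_name()
      if (!nm %in% names(alphabet)) fail(paste0("unknown monomer type: ", nm))
      node <- list(type = nm, children = list())
      for (b in branches) node <- attach_child(node, b[[1]], b$ac, b$dc)
      if (!is.null(pending)) node <- attach_child(node, pending[[1]],
                                                  pending$ac, pending$dc)
      if (peek() == "(") {
        l <- parse_linkage()
        pending <- list(node = node, ac = l[1], dc = l[2])
      } else {
        if (depth > 0L) fail("expected a linkage before ']'")
        if (pos <= n) fail("unexpected trailing input")
        return(node)
      }
    }
  }

  root <- parse_seq(0L)
  flatten_tree(root, alphabet)
}

# nested list (type, children = list(ac, dc, node)) -> glyc_oligomer
flatten_tree <- function(root, alphabet) {
  type <- character(0); parent <- integer(0); ac <- integer(0); dc <- integer(0)
  add <- function(node, parent_idx, node_ac, node_dc) {
    type <<- c(type, node$type)
    parent <<- c(parent, parent_idx)
    ac <<- c(ac, node_ac)
    dc <<- c(dc, node_dc)
    idx <- length(type)
    for (ch in node$children) add(ch$node, idx, ch$ac, ch$dc)
  }
  add(root, NA_integer_, NA_integer_, NA_integer_)
  new_oligomer(type, parent, ac, dc, alphabet)
}

#' Free attachment sites of an oligomer
#'
#' A site is a (node, carbon) pair where the carbon is an acceptor carbon of
#' the node's type and does not yet carry a branch: the positions at which an
#' enzyme could attach a new monomer.
#'
#' @param o A `glyc_oligomer`.
#' @return A tibble with columns `node` (node index), `carbon`, `type`
#'   (monomer type of the node) and `path` (list column: acceptor carbons
#'   from the root identifying the node).
#' @export
free_sites <- function(o) {
  n <- oligomer_size(o)
  nodes <- integer(0); carbons <- integer(0)
  for (i in dfs_order(o)) {
    acc <- o$alphabet[[o$type[i]]]$acceptor_carbons
    free <- setdiff(acc, occupied_carbons(o, i))
    nodes <- c(nodes, rep.int(i, length(free)))
    carbons <- c(carbons, free)
  }
  tibble::tibble(
    node = nodes, carbon = carbons, type = o$type[nodes],
    path = lapply(nodes, function(i) node_path(o, i))
  )
}

# depth-first preorder with children in ascending carbon order (iterative:
# oligomers can be arbitrarily deep chains)
dfs_order <- function(o) {
  n <- length(o$type)
  kids <- vector("list", n)
  if (n > 1L) {
    for (j in 2:n) {
      p <- o$parent[j]
      kids[[p]] <- c(kids[[p]], j)
    }
  }
  out <- integer(n)
  stack <- 1L
  pos <- 0L
  while (length(stack) > 0L) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pos <- pos + 1L
    out[pos] <- i
    ch <- kids[[i]]
    if (length(ch) > 0L) {
      ch <- ch[order(o$ac[ch], decreasing = TRUE)] # pop ascending
      stack <- c(stack, ch)
    }
  }
  out
}

#' @rdname free_sites
#' @param i Node index.
#' @return `node_path()` returns the acceptor carbons followed from the root
#'   to reach node `i` (integer vector, empty for the root).
#' @export
node_path <- function(o, i) {
  path <- integer(0)
  while (!is.na(o$parent[i])) {
    path <- c(o$ac[i], path)
    i <- o$parent[i]
  }
  path
}

#' @rdname free_sites
#' @param path Integer vector of acceptor carbons from the root.
#' @return `resolve_path()` returns the node index reached by `path`.
#' @export
resolve_path <- function(o, path) {
  i <- 1L
  for (carbon in path) {
    ch <- children_of(o, i)
    hit <- ch[o$ac[ch] == carbon]
    if (length(hit) != 1L) {
      stop("path does not resolve to a node: no branch at carbon ", carbon,
           call. = FALSE)
    }
    i <- hit
  }
  i
}

#' Attach one monomer to a free site
#'
#' The elementary growth step: a new leaf of type `donor` is attached at the
#' free `carbon` of node `node`, bonded through `donor_carbon` of the new
#' monomer. Additions are irreversible; the input oligomer is unchanged
#' (copy-on-write).
#'
#' @param o A `glyc_oligomer`.
#' @param node Node index of the acceptor monomer (or an integer path as
#'   produced by [node_path()], passed via `path`).
#' @param carbon Free acceptor carbon on that node.
#' @param donor Name of the monomer type to attach.
#' @param donor_carbon Carbon of the donor used in the new bond; defaults to
#'   the donor type's declared donor carbon.
#' @param path Alternative to `node`: identify the acceptor by path.
#' @return A new `glyc_oligomer`, one monomer larger.
#' @export
add_monomer <- function(o, node = NULL, carbon, donor, donor_carbon = NULL,
                        path = NULL) {
  if (is.null(node)) {
    if (is.null(path)) stop("give either node or path", call. = FALSE)
    node <- resolve_path(o, path)
  }
  if (!donor %in% names(o$alphabet)) {
    stop("unknown donor type: ", donor, call. = FALSE)
  }
  donor_carbon <- donor_carbon %||% o$alphabet[[donor]]$donor_carbon
  acc <- o$alphabet[[o$type[node]]]$acceptor_carbons
  if (!carbon %in% acc) {
    stop("carbon ", carbon, " is not an acceptor carbon of ", o$type[node],
         call. = FALSE)
  }
  if (carbon %in% occupied_carbons(o, node)) {
    stop("carbon ", carbon, " of node ", node, " is already occupied",
         call. = FALSE)
  }
  new_oligomer(
    type = c(o$type, donor),
    parent = c(o$parent, as.integer(node)),
    ac = c(o$ac, as.integer(carbon)),
    dc = c(o$dc, as.integer(donor_carbon)),
    alphabet = o$alphabet
  )
}

#' Enumerate all sub-oligomers of a target
#'
#' A sub-oligomer is a connected subtree that contains the root: exactly the
#' possible intermediates of a monomer-by-monomer growth of the target from
#' its root. The root monomer alone and the target itself are included.
#'
#' @param target A `glyc_oligomer`.
#' @return A list of `glyc_oligomer`s, ordered by increasing size and then
#'   canonical string; no duplicates (structurally equal sub-oligomers
#'   arising from different node subsets are kept once).
#' @export
enumerate_sub_oligomers <- function(target) {
  node_sets <- sub_node_sets(target, 1L)
  subs <- lapply(node_sets, function(keep) induced_oligomer(target, keep))
  keys <- vapply(subs, serialize_canonical, character(1))
  keep <- !duplicated(keys)
  subs <- subs[keep]
  keys <- keys[keep]
  sizes <- vapply(subs, oligomer_size, integer(1))
  subs[order(sizes, keys)]
}

# all node subsets forming a connected subtree rooted at i (containing i)
sub_node_sets <- function(o, i) {
  ch <- children_of(o, i)
  options <- lapply(ch, function(c_) c(list(NULL), sub_node_sets(o, c_)))
  sets <- list(integer(0))
  for (opt in options) {
    sets <- unlist(lapply(sets, function(s) {
      lapply(opt, function(x) c(s, x))
    }), recursive = FALSE)
  }
  lapply(sets, function(s) c(i, s))
}

# restriction of o to a node subset that forms a root-containing subtree
induced_oligomer <- function(o, keep) {
  keep <- sort(unique(as.integer(keep)))
  remap <- match(seq_along(o$type), keep)
  new_oligomer(
    type = o$type[keep],
    parent = ifelse(is.na(o$parent[keep]), NA_integer_, remap[o$parent[keep]]),
    ac = o$ac[keep],
    dc = o$dc[keep],
    alphabet = o$alphabet
  )
}

# o restricted to node i and everything below it (i becomes the root);
# used when comparing branch subtrees against enzyme patterns
extract_subtree <- function(o, i) {
  keep <- i
  frontier <- i
  while (length(frontier) > 0L) {
    nxt <- which(!is.na(o$parent) & o$parent %in% frontier)
    keep <- c(keep, nxt)
    frontier <- nxt
  }
  keep <- sort(unique(keep))
  remap <- match(seq_along(o$type), keep)
  parent <- remap[o$parent[keep]]
  ac <- o$ac[keep]
  dc <- o$dc[keep]
  rootpos <- match(i, keep)
  parent[rootpos] <- NA_integer_
  ac[rootpos] <- NA_integer_
  dc[rootpos] <- NA_integer_
  # reorder so the subtree root becomes node 1
  idx <- c(rootpos, setdiff(seq_along(keep), rootpos))
  remap2 <- match(seq_along(keep), idx)
  new_oligomer(
    type = o$type[keep][idx],
    parent = remap2[parent[idx]],
    ac = ac[idx],
    dc = dc[idx],
    alphabet = o$alphabet
  )
}

#' @method as_tibble glyc_oligomer
#' @export
as_tibble.glyc_oligomer <- function(x, ...) {
  n <- oligomer_size(x)
  tibble::tibble(
    node = seq_len(n),
    type = x$type,
    parent = x$parent,
    acceptor_carbon = x$ac,
    donor_carbon = x$dc,
    path = lapply(seq_len(n), function(i) node_path(x, i))
  )
}

#' Export or import an oligomer as JSON
#'
#' The JSON layout lists nodes (id, type) and edges (parent, child, carbon
#' pair) for interoperability with graph tools.
#'
#' @param o A `glyc_oligomer`.
#' @param path Optional file; when `NULL`, the JSON string is returned.
#' @param json A JSON string or file path.
#' @param alphabet Alphabet used to rebuild the oligomer.
#' @return `oligomer_to_json()` returns a JSON string (or writes a file);
#'   `oligomer_from_json()` returns a `glyc_oligomer`.
#' @export
oligomer_to_json <- function(o, path = NULL) {
  n <- oligomer_size(o)
  obj <- list(
    nodes = data.frame(id = seq_len(n), type = o$type),
    edges = if (n > 1L) {
      data.frame(parent = o$parent[-1L], child = 2:n,
                 acceptor_carbon = o$ac[-1L], donor_carbon = o$dc[-1L])
    } else {
      data.frame(parent = integer(0), child = integer(0),
                 acceptor_carbon = integer(0), donor_carbon = integer(0))
    }
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE)
  } else {
    jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE)
    invisible(path)
  }
}

#' @rdname oligomer_to_json
#' @export
oligomer_from_json <- function(json, alphabet) {
  obj <- jsonlite::fromJSON(json)
  n <- nrow(obj$nodes)
  parent <- rep(NA_integer_, n); ac <- rep(NA_integer_, n)
  dc <- rep(NA_integer_, n)
  if (n > 1L) {
    parent[obj$edges$child] <- obj$edges$parent
    ac[obj$edges$child] <- obj$edges$acceptor_carbon
    dc[obj$edges$child] <- obj$edges$donor_carbon
  }
  o <- new_oligomer(obj$nodes$type, parent, ac, dc, alphabet)
  validate_oligomer(o)
  o
}
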