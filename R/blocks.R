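#' Detect acceptor blocks between enzyme pairs
#'
#' An acceptor block is the structural condition behind divergent reactions:
#' the action of one enzyme can forbid the subsequent action of another.
#' Blocks are necessary (not sufficient) for divergence.
#'
#' * Bidirectional (all classes): two enzymes compete for the same acceptor
#'   substrate — overlapping acceptor motifs on the same type and the same
#'   acceptor carbon, with different additions. Whichever fires first
#'   occupies the carbon and blocks the other.
#' * Unidirectional (branch-sensitive only): one enzyme's action destroys
#'   another's branch requirement — the blocker's acceptor motif lies on a
#'   required branch of the blocked enzyme (extending the branch breaks the
#'   ideal full-subtree match), or the blocker fills a carbon the blocked
#'   enzyme requires to be empty, or starts growing a branch the blocked
#'   enzyme forbids.
#'
#' Detection is symbolic on the motifs; whether a block is actually realized
#' on a given input is what [detect_divergence()] decides dynamically.
#'
#' @param c A [compartment()].
#' @return A tibble with columns `blocker`, `blocked`, `direction`
#'   (`"bidirectional"` rows appear once per unordered pair, with the two
#'   names in either slot; `"unidirectional"` rows are ordered).
#' @export
detect_acceptor_blocks <- function(c) {
  stopifnot(inherits(c, "glyc_compartment"))
  es <- c$enzymes
  blocker <- character(0); blocked <- character(0); direction <- character(0)
  nms <- names(es)
  for (i in seq_along(es)) {
    for (j in seq_along(es)) {
      if (i == j) next
      e1 <- es[[i]]; e2 <- es[[j]]
      if (i < j && bidirectional_block(e1, e2)) {
        blocker <- c(blocker, nms[i]); blocked <- c(blocked, nms[j])
        direction <- c(direction, "bidirectional")
      }
      if (unidirectional_block(e1, e2)) {
        blocker <- c(blocker, nms[i]); blocked <- c(blocked, nms[j])
        direction <- c(direction, "unidirectional")
      }
    }
  }
  tibble::tibble(blocker = blocker, blocked = blocked, direction = direction)
}

# same acceptor substrate, same carbon, different addition
bidirectional_block <- function(e1, e2) {
  if (e1$acceptor_type != e2$acceptor_type) return(FALSE)
  if (e1$acceptor_carbon != e2$acceptor_carbon) return(FALSE)
  same_addition <- e1$donor_type == e2$donor_type &&
    e1$donor_carbon == e2$donor_carbon
  if (same_addition) return(FALSE) # identical reaction, fork reconverges trivially
  motifs_overlap(e1, e2)
}

# can some acceptor node satisfy both enzymes' context constraints at once?
motifs_overlap <- function(e1, e2) {
  if (e1$class == "context_free" || e2$class == "context_free") return(TRUE)
  if (e1$class == "root_sensitive" && e2$class == "root_sensitive") {
    return(identical(root_chain_string(e1$root_chain),
                     root_chain_string(e2$root_chain)))
  }
  if (e1$class != "branch_sensitive" || e2$class != "branch_sensitive") {
    # one RS, one BS: root and branch constraints are independent
    return(TRUE)
  }
  ok_pair <- function(a, b) {
    # a required vs b's constraints on the same carbon
    for (ra in a$required_branches) {
      for (rb in b$required_branches) {
        if (ra$carbon == rb$carbon &&
            !(ra$dc == rb$dc &&
              subtree_string(ra$pattern, 1L) == subtree_string(rb$pattern, 1L))) {
          return(FALSE)
        }
      }
      for (fb in b$forbidden_branches) {
        if (ra$carbon != fb$carbon) next
        if (identical(fb$pattern, "*")) return(FALSE)
        if (ra$dc == fb$dc &&
            subtree_string(ra$pattern, 1L) == subtree_string(fb$pattern, 1L)) {
          return(FALSE)
        }
      }
    }
    TRUE
  }
  ok_pair(e1, e2) && ok_pair(e2, e1)
}

# does e1's action destroy e2's branch requirements (branch-sensitive only)?
unidirectional_block <- function(e1, e2) {
  if (e2$class != "branch_sensitive") return(FALSE)
  if (e1$class == "root_sensitive") return(FALSE)
  # (a) e1 can extend a required branch subtree, breaking the ideal
  # full-subtree match
  for (rb in e2$required_branches) {
    if (nrow(match_sites(e1, rb$pattern)) > 0L) return(TRUE)
  }
  # (b)/(c) e1 fills a carbon e2 needs empty, or starts a forbidden branch
  if (e1$acceptor_type == e2$acceptor_type) {
    for (fb in e2$forbidden_branches) {
      if (e1$acceptor_carbon != fb$carbon) next
      if (identical(fb$pattern, "*")) {
        if (motifs_overlap(e1, e2)) return(TRUE)
      } else if (e1$donor_type == fb$pattern$type[1L] &&
                 e1$donor_carbon == fb$dc) {
        if (motifs_overlap(e1, e2)) return(TRUE)
      }
    }
  }
  FALSE
}
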