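# Ranked species trees: edge subdivision into time slices.
#
# A ranking pi induces a unary-binary tree S^pi: for every internal node u
# (in increasing rank order) and every edge (p(v), v) spanning u's rank
# (pi(p(v)) < pi(u) < pi(v)), a unary node is inserted on the edge.  The
# time slice t(i) then holds the single node of rank i plus the unary
# nodes inserted at rank i: all lineages alive at that moment.  Slice k is
# the set of extant species.  Transfers in ranked models are restricted to
# contemporaries, i.e. to the donor's slice.

#' Subdivide a ranked species tree into time slices
#'
#' Builds the unary-binary tree induced by a ranking.  An inserted unary
#' node standing for species `v` in slice `i` is labeled by `v`'s label
#' followed by one prime per slice it is below `p(v)` (so the node for C
#' one slice under its parent prints as `C'`).
#'
#' @param tree a `species_tree` with k leaves.
#' @param ranking a `tree_ranking` for `tree`, e.g. from
#'   [random_ranking()] or [ranking_from_order()].
#' @return an object of class `time_sliced_tree` with fields `labels`,
#'   `children` (length 0, 1 or 2), `parent`, `slice` (1..k), and
#'   `species` mapping every node to the underlying species-tree node.
#' @examples
#' tr <- make_complete_binary(2)
#' rk <- random_ranking(tr, seed = 1)
#' build_time_slices(tr, rk)
#' @export
build_time_slices <- function(tree, ranking) {
  stopifnot(inherits(tree, "species_tree"), inherits(ranking, "tree_ranking"))
  if (!identical(ranking$labels, tree$labels))
    stop("ranking was built for a different tree")
  validate_ranking(tree, ranking$rank)
  k <- tree$k
  n0 <- n_nodes(tree)
  labels <- tree$labels
  children <- tree$children
  species <- seq_len(n0)
  slice <- ranking$rank
  parent <- tree$parent
  new_node <- function(lab, sp, sl) {
    labels[[length(labels) + 1L]] <<- lab
    children[[length(children) + 1L]] <<- integer(0)
    species[[length(species) + 1L]] <<- sp
    slice[[length(slice) + 1L]] <<- sl
    parent[[length(parent) + 1L]] <<- NA_integer_
    length(labels)
  }
  for (v in seq_len(n0)) {
    p <- tree$parent[v]
    if (is.na(p)) next
    rp <- ranking$rank[p]; rv <- slice[v]
    if (rv - rp <= 1L) next
    chain <- p
    for (i in seq.int(rp + 1L, rv - 1L)) {
      u <- new_node(paste0(tree$labels[v], strrep("'", i - rp)), v, i)
      chain <- c(chain, u)
    }
    chain <- c(chain, v)
    # rewire: replace v in p's child slot by the first unary node
    children[[p]][children[[p]] == v] <- chain[2L]
    for (j in 2:(length(chain) - 1L)) {
      children[[chain[j]]] <- chain[j + 1L]
      parent[chain[j]] <- chain[j - 1L]
    }
    parent[v] <- chain[length(chain) - 1L]
  }
  out <- structure(list(labels = unlist(labels), children = children,
                        parent = parent,
                        root = tree$root, k = k,
                        slice = unlist(slice), species = unlist(species),
                        base = tree, ranking = ranking),
                   class = "time_sliced_tree")
  # invariant: slice i has exactly i nodes, slice k holds the k leaves
  sz <- tabulate(out$slice, nbins = k)
  stopifnot(identical(sz, seq_len(k)))
  out
}

#' @export
print.time_sliced_tree <- function(x, ...) {
  cat("Time-sliced species tree, k = ", x$k, " (",
      length(x$labels), " nodes)\n", sep = "")
  for (i in seq_len(x$k)) {
    cat("  slice ", i, ": {",
        paste(x$labels[x$slice == i], collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}

slice_members <- function(sliced, i) which(sliced$slice == i)

## ---- incomparability ----

#' Nodes incomparable with a given node
#'
#' For an unranked `species_tree`, returns all nodes that are neither
#' ancestors nor descendants of `u` — the admissible receivers of a
#' horizontal transfer out of `u` in the unranked DLT model.  For a
#' `time_sliced_tree`, returns the other members of `u`'s time slice
#' (contemporaneous lineages), the admissible receivers in the ranked
#' models.
#'
#' @param context a `species_tree` or `time_sliced_tree`.
#' @param u a node label.
#' @return a character vector of node labels (possibly empty).
#' @examples
#' incomparable(make_complete_binary(2), "s1")
#' @export
incomparable <- function(context, u) UseMethod("incomparable")

#' @export
incomparable.species_tree <- function(context, u) {
  i <- node_id(context, u)
  context$labels[incomparable_ids(context)[[i]]]
}

#' @export
incomparable.time_sliced_tree <- function(context, u) {
  i <- node_id(context, u)
  context$labels[setdiff(slice_members(context, context$slice[i]), i)]
}

# internal: list of incomparable node id sets, memoised on the object
incomparable_ids <- function(context) {
  if (inherits(context, "time_sliced_tree")) {
    return(lapply(seq_along(context$labels), function(i)
      setdiff(slice_members(context, context$slice[i]), i)))
  }
  n <- n_nodes(context)
  anc <- vector("list", n) # ancestors incl. self
  for (i in seq_len(n)) {
    a <- i
    p <- context$parent[i]
    while (!is.na(p)) { a <- c(a, p); p <- context$parent[p] }
    anc[[i]] <- a
  }
  lapply(seq_len(n), function(i) {
    comp <- unique(c(anc[[i]], which(vapply(anc, function(a) i %in% a, TRUE))))
    setdiff(seq_len(n), comp)
  })
}
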