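# Species trees: uniquely labeled rooted binary trees over extant species.
#
# A tree is stored as parallel vectors indexed by integer node ids:
# `labels` (unique), `children` (list of integer vectors, length 2 for
# internal nodes and 0 for leaves), `parent` (NA at the root).  Unordered
# trees are made ordered by sorting the two children of every internal
# node by their labels (C-locale radix order), so structurally equal trees
# have identical representations.

label_order <- function(x) order(x, method = "radix")

new_species_tree <- function(labels, children) {
  n <- length(labels)
  stopifnot(length(children) == n)
  if (anyDuplicated(labels)) {
    stop("duplicate node labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ch <- children[[i]]
    if (length(ch) == 0L) next
    if (length(ch) != 2L) stop("species trees must be binary (node '",
                               labels[i], "' has ", length(ch), " children)")
    ch <- ch[label_order(labels[ch])]
    children[[i]] <- as.integer(ch)
    parent[ch] <- i
  }
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("tree must have exactly one root")
  structure(list(labels = labels, children = children,
                 parent = parent, root = root,
                 k = sum(lengths(children) == 0L)),
            class = "species_tree")
}

is_leaf_node <- function(tree, i) length(tree$children[[i]]) == 0L

n_nodes <- function(tree) length(tree$labels)

node_id <- function(tree, label) {
  i <- match(label, tree$labels)
  if (is.na(i)) stop("no node labeled '", label, "' in tree")
  i
}

# leaves in left-to-right order of the ordered tree
leaves_in_order <- function(tree) {
  out <- integer(0)
  walk <- function(i) {
    ch <- tree$children[[i]]
    if (length(ch) == 0L) out[[length(out) + 1L]] <<- i
    else for (c in ch) walk(c)
  }
  walk(tree$root)
  unlist(out)
}

post_order <- function(tree) {
  out <- integer(0)
  walk <- function(i) {
    for (c in tree$children[[i]]) walk(c)
    out[[length(out) + 1L]] <<- i
  }
  walk(tree$root)
  unlist(out)
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Species tree with ", x$k, " leaves (", n_nodes(x), " nodes)\n",
      sep = "")
  cat(write_newick(x), "\n")
  invisible(x)
}

## ---- Newick I/O ----

#' Read a species tree from a Newick string
#'
#' Parses a rooted binary tree in Newick format.  Internal nodes may carry
#' labels; unlabeled internal nodes are given deterministic labels of the
#' form `@<smallest leaf label>_<subtree leaf count>`, which is unique for
#' every subtree.  Branch lengths are accepted and ignored.  The children
#' of every internal node are ordered by increasing label, so parsing the
#' output of [write_newick()] reproduces the tree exactly.
#'
#' @param text a Newick string (must end in `;`), or a file path when
#'   `file = TRUE`.
#' @param file logical; read `text` as a file path.
#' @return an object of class `species_tree`.
#' @examples
#' parse_newick("((A,B)X,C)R;")
#' @export
parse_newick <- function(text, file = FALSE) {
  if (file) text <- paste(readLines(text, warn = FALSE), collapse = "")
  text <- trimws(text)
  bare <- sub(";\\s*$", "", text)
  if (!grepl("[(),]", bare)) {
    # single-leaf tree, e.g. "A;" (ape cannot represent these)
    lab <- sub(":.*$", "", bare)
    if (nchar(lab) == 0L) stop("empty Newick string")
    return(new_species_tree(lab, list(integer(0))))
  }
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("malformed Newick string")
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  labels <- c(phy$tip.label, if (is.null(phy$node.label))
    rep("", phy$Nnode) else phy$node.label)
  labels[is.na(labels)] <- ""
  children <- vector("list", nn)
  for (i in seq_len(nn)) children[[i]] <- integer(0)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; c <- phy$edge[e, 2L]
    children[[p]] <- c(children[[p]], c)
  }
  if (any(lengths(children) %in% c(1L)) || any(lengths(children) > 2L)) {
    stop("species trees must be binary; found a node with ",
         max(lengths(children)), " children")
  }
  # deterministic auto-labels for unlabeled internals
  sm <- character(nn); nl <- integer(nn)
  fill <- function(i) {
    ch <- children[[i]]
    if (length(ch) == 0L) { sm[i] <<- labels[i]; nl[i] <<- 1L; return() }
    for (c in ch) fill(c)
    sm[i] <<- min(sm[ch])
    nl[i] <<- sum(nl[ch])
  }
  root <- setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
  fill(root)
  blank <- which(labels == "")
  labels[blank] <- paste0("@", sm[blank], "_", nl[blank])
  new_species_tree(labels, children)
}

#' Write a species tree as a canonical Newick string
#'
#' @param tree a `species_tree`.
#' @param internal_labels include internal node labels (default `TRUE`).
#' @return a Newick string with children in label order.
#' @export
write_newick <- function(tree, internal_labels = TRUE) {
  rec <- function(i) {
    ch <- tree$children[[i]]
    if (length(ch) == 0L) return(tree$labels[i])
    paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")",
           if (internal_labels) tree$labels[i] else "")
  }
  paste0(rec(tree$root), ";")
}

## ---- canonical tree families ----

leaf_labels <- function(k) sprintf(paste0("s%0", nchar(k), "d"), seq_len(k))

# build a species_tree from a nested structure: a character scalar (leaf
# label) or list(l, r)
tree_from_nested <- function(nested) {
  labels <- character(0); children <- list()
  add <- function(nd) {
    if (is.character(nd)) {
      labels[[length(labels) + 1L]] <<- nd
      children[[length(children) + 1L]] <<- integer(0)
      return(list(id = length(labels), sm = nd, nl = 1L))
    }
    l <- add(nd[[1L]]); r <- add(nd[[2L]])
    sm <- min(l$sm, r$sm); nl <- l$nl + r$nl
    labels[[length(labels) + 1L]] <<- paste0("@", sm, "_", nl)
    children[[length(children) + 1L]] <<- c(l$id, r$id)
    list(id = length(labels), sm = sm, nl = nl)
  }
  add(nested)
  new_species_tree(unlist(labels), children)
}

#' Caterpillar, complete binary, and balanced species trees
#'
#' `make_caterpillar(k)` builds the caterpillar tree CT_k: CT_1 is a
#' single leaf, and CT_k has CT_(k-1) as one subtree and a leaf as the
#' other.  `make_complete_binary(h)` builds CB_h with 2^h leaves, both
#' subtrees equal to CB_(h-1).  `make_balanced(k)` builds the balanced
#' tree in which every node splits its leaves as evenly as possible; when
#' k is a power of two this is exactly CB_(log2 k).  These two families
#' are the conjectured extremes for the number of duplication-loss
#' histories among all species trees of the same size.
#'
#' @param k number of leaves (k >= 1).
#' @param h height of the complete binary tree (h >= 0; 2^h leaves).
#' @return a `species_tree`.
#' @examples
#' make_caterpillar(5)
#' make_complete_binary(2)
#' @export
make_caterpillar <- function(k) {
  stopifnot(length(k) == 1L, k == floor(k))
  if (k < 1) stop("k must be >= 1")
  labs <- leaf_labels(k)
  nested <- labs[1L]
  if (k > 1) for (j in 2:k) nested <- list(nested, labs[j])
  tree_from_nested(nested)
}

#' @rdname make_caterpillar
#' @export
make_complete_binary <- function(h) {
  stopifnot(length(h) == 1L, h == floor(h))
  if (h < 0) stop("h must be >= 0")
  make_balanced(2^h)
}

#' @rdname make_caterpillar
#' @export
make_balanced <- function(k) {
  stopifnot(length(k) == 1L, k == floor(k))
  if (k < 1) stop("k must be >= 1")
  labs <- leaf_labels(k)
  split <- function(ix) {
    if (length(ix) == 1L) return(labs[ix])
    m <- ceiling(length(ix) / 2)
    list(split(ix[seq_len(m)]), split(ix[-seq_len(m)]))
  }
  tree_from_nested(split(seq_len(k)))
}

## ---- topology enumeration and uniform sampling ----

# unordered binary tree shapes as nested lists; leaf = "x"
all_shapes_memo <- new.env(parent = emptyenv())
all_shapes <- function(k) {
  key <- as.character(k)
  if (!is.null(all_shapes_memo[[key]])) return(all_shapes_memo[[key]])
  res <- if (k == 1L) list("x") else {
    out <- list()
    for (i in seq_len(k %/% 2)) {
      si <- all_shapes(i); sj <- all_shapes(k - i)
      if (i < k - i) {
        for (a in si) for (b in sj) out[[length(out) + 1L]] <- list(a, b)
      } else {
        for (ai in seq_along(si)) for (bi in ai:length(si))
          out[[length(out) + 1L]] <- list(si[[ai]], si[[bi]])
      }
    }
    out
  }
  all_shapes_memo[[key]] <- res
  res
}

shape_to_tree <- function(shape, k) {
  labs <- leaf_labels(k)
  i <- 0L
  fill <- function(s) {
    if (is.character(s)) { i <<- i + 1L; return(labs[i]) }
    list(fill(s[[1L]]), fill(s[[2L]]))
  }
  tree_from_nested(fill(shape))
}

#' Enumerate all distinct species-tree topologies with k leaves
#'
#' Returns one `species_tree` per distinct unordered binary tree shape
#' with `k` leaves (there are Wedderburn-Etherington many: 1, 1, 1, 2, 3,
#' 6, 11, ... shapes for k = 1, 2, ...), with leaves labeled left to
#' right.
#'
#' @param k number of leaves.
#' @return a list of `species_tree` objects.
#' @export
enumerate_topologies <- function(k) {
  stopifnot(k >= 1, k == floor(k))
  if (k > 14) stop("topology enumeration is limited to k <= 14")
  lapply(all_shapes(k), shape_to_tree, k = k)
}

shape_canonical <- function(s) {
  if (is.character(s)) return("x")
  a <- shape_canonical(s[[1L]]); b <- shape_canonical(s[[2L]])
  if (a <= b) paste0("(", a, ",", b, ")") else paste0("(", b, ",", a, ")")
}

wedderburn_etherington <- function(k) {
  w <- numeric(k); w[1L] <- 1
  for (m in seq_len(k)[-1L]) {
    tot <- 0
    for (i in seq_len(m %/% 2)) {
      tot <- tot + if (i < m - i) w[i] * w[m - i] else w[i] * (w[i] + 1) / 2
    }
    w[m] <- tot
  }
  w
}

#' Draw a species-tree topology uniformly at random
#'
#' Samples uniformly over the distinct unordered binary tree shapes with
#' `k` leaves by the counting-based recursive method on the
#' Wedderburn-Etherington recurrence, then labels the leaves left to
#' right.  Equal-size splits use a rejection step so that unordered pairs
#' of subtree shapes are equally likely.
#'
#' @param k number of leaves.
#' @param seed integer seed; the same `(k, seed)` always returns the same
#'   tree.
#' @return a `species_tree`.
#' @export
random_topology <- function(k, seed = NULL) {
  stopifnot(k >= 1, k == floor(k), k <= 40)
  if (!is.null(seed)) set.seed(seed)
  w <- wedderburn_etherington(max(k, 1L))
  rshape <- function(m) {
    if (m == 1L) return("x")
    half <- m %/% 2
    wt <- vapply(seq_len(half), function(i) {
      if (i < m - i) w[i] * w[m - i] else w[i] * (w[i] + 1) / 2
    }, 0)
    i <- sample.int(half, 1L, prob = wt)
    if (i < m - i) return(list(rshape(i), rshape(m - i)))
    repeat {
      a <- rshape(i); b <- rshape(i)
      if (shape_canonical(a) == shape_canonical(b) || stats::runif(1) < 0.5)
        return(list(a, b))
    }
  }
  shape_to_tree(rshape(k), k)
}

## ---- rankings ----

validate_ranking <- function(tree, rank) {
  k <- tree$k
  stopifnot(length(rank) == n_nodes(tree))
  internal <- which(lengths(tree$children) == 2L)
  leaves <- which(lengths(tree$children) == 0L)
  if (any(rank[leaves] != k)) stop("all leaves must have rank k")
  ir <- rank[internal]
  if (length(internal) > 0 &&
      (anyDuplicated(ir) || !setequal(ir, seq_len(k - 1L))))
    stop("internal ranks must be a permutation of 1..k-1")
  for (i in internal) {
    p <- tree$parent[i]
    if (!is.na(p) && rank[p] >= rank[i])
      stop("ancestors must have strictly smaller ranks (node '",
           tree$labels[i], "')")
  }
  invisible(TRUE)
}

new_ranking <- function(tree, rank) {
  validate_ranking(tree, rank)
  structure(list(rank = as.integer(rank), k = tree$k,
                 labels = tree$labels),
            class = "tree_ranking")
}

#' Build a ranking from internal-node labels in rank order
#'
#' A ranking assigns ranks 1..k-1 to the internal nodes (strictly
#' increasing from the root down: ancestors speciate earlier) and rank k
#' to every leaf.  It records the relative order of speciation events.
#'
#' @param tree a `species_tree` with k leaves.
#' @param order_labels character vector of the k-1 internal node labels,
#'   earliest speciation first.
#' @return an object of class `tree_ranking`.
#' @export
ranking_from_order <- function(tree, order_labels) {
  internal <- which(lengths(tree$children) == 2L)
  if (!setequal(order_labels, tree$labels[internal]))
    stop("order_labels must be exactly the internal node labels")
  rank <- rep(tree$k, n_nodes(tree))
  rank[match(order_labels, tree$labels)] <- seq_along(order_labels)
  new_ranking(tree, rank)
}

#' @export
print.tree_ranking <- function(x, ...) {
  internal <- order(x$rank)[seq_len(sum(x$rank < x$k))]
  cat("Ranking (earliest first): ",
      paste(x$labels[internal], collapse = " < "), "\n", sep = "")
  invisible(x)
}

#' Draw a ranking uniformly over all rankings of a tree
#'
#' Rankings of a species tree are exactly the linear extensions of its
#' internal-node ancestry poset.  The sampler repeatedly picks the next
#' internal node among the currently available subtree roots with
#' probability proportional to the number of internal nodes in its
#' subtree, which by the hook length formula for forests yields the
#' uniform distribution over linear extensions.
#'
#' @param tree a `species_tree`.
#' @param seed integer seed (deterministic given `(tree, seed)`).
#' @return a `tree_ranking`.
#' @export
random_ranking <- function(tree, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_nodes(tree)
  internal <- lengths(tree$children) == 2L
  isize <- integer(n) # number of internal nodes in subtree
  for (i in post_order(tree)) {
    isize[i] <- if (internal[i]) 1L + sum(isize[tree$children[[i]]]) else 0L
  }
  rank <- rep(tree$k, n)
  avail <- if (internal[tree$root]) tree$root else integer(0)
  r <- 0L
  while (length(avail) > 0L) {
    r <- r + 1L
    pick <- if (length(avail) == 1L) avail else
      avail[sample.int(length(avail), 1L, prob = isize[avail])]
    rank[pick] <- r
    avail <- setdiff(avail, pick)
    kids <- tree$children[[pick]]
    avail <- c(avail, kids[internal[kids]])
  }
  new_ranking(tree, rank)
}

#' Enumerate all rankings of a species tree
#'
#' Exhaustively lists the linear extensions of the internal-node poset.
#' Intended for small trees (k <= 7).
#'
#' @param tree a `species_tree`.
#' @return a list of `tree_ranking` objects.
#' @export
enumerate_rankings <- function(tree) {
  internal <- lengths(tree$children) == 2L
  if (tree$k > 8) stop("ranking enumeration is limited to k <= 8")
  res <- list()
  rank <- rep(tree$k, n_nodes(tree))
  rec <- function(avail, r) {
    if (length(avail) == 0L) {
      res[[length(res) + 1L]] <<- new_ranking(tree, rank)
      return()
    }
    for (pick in avail) {
      rank[pick] <<- r
      kids <- tree$children[[pick]]
      rec(c(setdiff(avail, pick), kids[internal[kids]]), r + 1L)
      rank[pick] <<- tree$k
    }
  }
  rec(if (internal[tree$root]) tree$root else integer(0), 1L)
  res
}
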