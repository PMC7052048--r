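# The events graph of a ranked species tree, and the species-tree
# independence of the rDT-SL model.
#
# Label the k extant species 1..k left to right and label every node of
# the time-sliced tree with the set of leaves its subtree reaches.  Add
# speciation super-edges to the children, a duplication self-loop at
# every node, and transfer edges between all pairs of contemporaries
# (same time slice).  In the speciation-loss model every history can be
# rewritten on this graph: delete loss leaves, then label every node by
# the pair (its time slice, its leftmost extant descendant leaf) — the
# unique graph node of that slice containing that leaf.  Re-labeling the
# encoded tree against the events graph of any other ranked tree of the
# same size yields a valid history there, which is a size-preserving
# bijection: the rDT-SL history count does not depend on the tree.

#' Build the events graph of a time-sliced species tree
#'
#' @param sliced a `time_sliced_tree` from [build_time_slices()].
#' @return an object of class `events_graph`: list with the underlying
#'   `sliced` tree, `leafset` (per node, sorted integer leaf labels
#'   1..k), `slices` (node ids per slice), `k`, and `node_at` (matrix:
#'   `node_at[t, i]` is the node of slice t whose leaf set contains leaf
#'   i).
#' @examples
#' tr <- make_complete_binary(2)
#' g <- build_events_graph(build_time_slices(tr, random_ranking(tr, 1)))
#' @export
build_events_graph <- function(sliced) {
  stopifnot(inherits(sliced, "time_sliced_tree"))
  k <- sliced$k
  nn <- length(sliced$labels)
  lvs <- leaves_in_order(sliced)
  leafno <- integer(nn)
  leafno[lvs] <- seq_len(k)
  leafset <- vector("list", nn)
  for (i in post_order(sliced)) {
    ch <- sliced$children[[i]]
    leafset[[i]] <- if (length(ch) == 0L) leafno[i] else
      sort(unlist(leafset[ch]))
  }
  slices <- lapply(seq_len(k), function(t) which(sliced$slice == t))
  node_at <- matrix(NA_integer_, k, k)
  for (t in seq_len(k)) {
    cover <- sort(unlist(leafset[slices[[t]]]))
    if (!identical(cover, seq_len(k)))
      stop("slice ", t, " leaf sets do not partition 1..k")
    for (u in slices[[t]]) node_at[t, leafset[[u]]] <- u
  }
  structure(list(sliced = sliced, leafset = leafset, slices = slices,
                 k = k, node_at = node_at),
            class = "events_graph")
}

#' @export
print.events_graph <- function(x, ...) {
  cat("Events graph, k = ", x$k, "\n", sep = "")
  for (t in seq_len(x$k)) {
    sets <- vapply(x$slices[[t]], function(u)
      paste0("{", paste(x$leafset[[u]], collapse = ","), "}"), "")
    cat("  slice ", t, ": ", paste(sets, collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Export an events graph in GraphViz DOT format
#'
#' Speciation super-edges are solid, duplication self-loops dashed, and
#' within-slice transfer edges dotted.
#'
#' @param graph an `events_graph`.
#' @return a character scalar with DOT source.
#' @export
events_graph_dot <- function(graph) {
  s <- graph$sliced
  nm <- function(u) sprintf("\"t%d:%s\"", s$slice[u],
                            paste(graph$leafset[[u]], collapse = ""))
  lines <- c("digraph events {")
  for (u in seq_along(s$labels)) {
    for (c in s$children[[u]])
      lines <- c(lines, paste0("  ", nm(u), " -> ", nm(c), ";"))
    lines <- c(lines, paste0("  ", nm(u), " -> ", nm(u),
                             " [style=dashed];"))
  }
  for (t in seq_len(graph$k)) {
    for (u in graph$slices[[t]]) for (v in graph$slices[[t]])
      if (u != v) lines <- c(lines, paste0("  ", nm(u), " -> ", nm(v),
                                           " [style=dotted];"))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Count rDT-SL histories
#'
#' The speciation-loss model: duplications and within-slice transfers as
#' in rDLT, but every speciation is immediately followed by the loss of
#' one of the two lineages, so a speciation never increases the number
#' of gene copies.  By the events-graph bijection the resulting counts
#' depend only on the tree size k, not on the topology or ranking.
#'
#' @param sliced a `time_sliced_tree`.
#' @param n_max largest history size to tabulate.
#' @return a `count_tables` object (model `rDTSL`).
#' @export
count_dtsl <- function(sliced, n_max) {
  build_count_tables(sliced, "rDTSL", n_max)
}

## ---- encoding, decoding, transport ----

#' Encode an rDT-SL history over the events graph
#'
#' Deletes loss leaves and labels every remaining node by the pair (time
#' slice, leftmost extant descendant leaf).  The encoding is invertible
#' given the events graph ([decode_history()]), and re-interpreting it on
#' the events graph of another ranked tree of the same size
#' ([transport_history()]) realizes the counting bijection.
#'
#' @param h a valid rDT-SL `gene_history` on `graph`'s tree.
#' @param graph an `events_graph`.
#' @return an object of class `encoded_history`: nested nodes
#'   `list(slice, leaf, children)`.
#' @export
encode_history <- function(h, graph) {
  s <- graph$sliced
  bad <- validate_history(h, s, "rDTSL")
  if (nrow(bad) > 0L)
    stop("not a valid rDT-SL history: ", bad$problem[1L],
         " (node ", bad$node[1L], ")")
  rec <- function(node) {
    if (node$event == "L") return(NULL)
    u <- node_id(s, node$species)
    kids <- Filter(Negate(is.null), lapply(node$children, rec))
    leafno <- if (length(kids) == 0L) graph$leafset[[u]] else kids[[1L]]$leaf
    list(slice = s$slice[u], leaf = leafno, children = kids)
  }
  structure(rec(h), class = "encoded_history")
}

#' @export
print.encoded_history <- function(x, ...) {
  rec <- function(nd) {
    own <- paste0(nd$slice, ":", nd$leaf)
    if (length(nd$children) == 0L) return(own)
    paste0("(", paste(vapply(nd$children, rec, ""), collapse = ","), ")", own)
  }
  cat("Encoded rDT-SL history: ", rec(x), ";\n", sep = "")
  invisible(x)
}

#' Decode an encoded history against an events graph
#'
#' Inverts [encode_history()]: resolves each (slice, leaf) label to the
#' unique events-graph node of that slice containing the leaf, reads the
#' event type off the traversed edge (speciation to the next slice,
#' duplication self-loop, transfer within the slice), and reinserts the
#' forced loss leaf on the non-surviving side of every binary
#' speciation.
#'
#' @param enc an `encoded_history`.
#' @param graph an `events_graph` of the same size k.
#' @return a `gene_history` valid for `graph`'s tree under `rDTSL`.
#' @export
decode_history <- function(enc, graph) {
  s <- graph$sliced
  k <- graph$k
  resolve <- function(t, i) {
    if (t < 1L || t > k || i < 1L || i > k)
      stop("encoded label (", t, ", ", i, ") out of range for k = ", k)
    graph$node_at[t, i]
  }
  rec <- function(nd) {
    g <- resolve(nd$slice, nd$leaf)
    lab <- s$labels[g]
    nc <- length(nd$children)
    if (nc == 0L) {
      if (nd$slice != k) stop("extant leaf encoded outside the last slice")
      return(hnode("Extant", lab))
    }
    if (nc == 1L) {
      child <- nd$children[[1L]]
      if (child$slice != nd$slice + 1L)
        stop("speciation edge must go to the next time slice")
      gc <- resolve(child$slice, child$leaf)
      ch <- s$children[[g]]
      if (!(gc %in% ch)) stop("encoded speciation child is not a child ",
                              "of the parent node")
      if (length(ch) == 1L) return(hnode("S", lab, list(rec(child))))
      lost <- setdiff(ch, gc)
      kids <- if (ch[1L] == gc)
        list(rec(child), hnode("L", s$labels[lost]))
      else list(hnode("L", s$labels[lost]), rec(child))
      return(hnode("S", lab, kids))
    }
    if (nc == 2L) {
      lch <- nd$children[[1L]]; rch <- nd$children[[2L]]
      if (lch$slice != nd$slice || rch$slice != nd$slice)
        stop("duplication/transfer children must stay in the time slice")
      gl <- resolve(lch$slice, lch$leaf)
      if (gl != g) stop("original copy must keep the donor's label")
      gr <- resolve(rch$slice, rch$leaf)
      ev <- if (gr == g) "D" else "T"
      return(hnode(ev, lab, list(rec(lch), rec(rch))))
    }
    stop("encoded nodes have at most two children")
  }
  as_history(rec(enc))
}

#' Transport an rDT-SL history to another ranked species tree
#'
#' Because the encoding only uses (time slice, leaf number) pairs, an
#' encoded history can be decoded against the events graph of any other
#' ranked species tree with the same number of leaves.  The map is a
#' bijection between the history sets of the two trees and preserves the
#' history size.
#'
#' @param enc an `encoded_history` (from `src`'s tree).
#' @param src the `events_graph` the encoding came from.
#' @param dst the target `events_graph`.
#' @return a `gene_history` for `dst`'s tree.
#' @export
transport_history <- function(enc, src, dst) {
  stopifnot(inherits(enc, "encoded_history"),
            inherits(src, "events_graph"), inherits(dst, "events_graph"))
  if (src$k != dst$k)
    stop("transport needs ranked trees of the same size (",
         src$k, " vs ", dst$k, ")")
  decode_history(enc, dst)
}

## ---- iterative tree-growing oracle ----

#' Generate all rDT-SL histories by iterative leaf expansion
#'
#' An independent second construction of the rDT-SL history set: grow
#' encoded trees over the events graph, starting from a root labeled
#' with slice 1 and each possible tracked leaf, repeatedly expanding the
#' leftmost unfinished leaf by one outgoing edge (speciation to the next
#' slice, duplication, or transfer; a slice-k leaf may terminate as
#' extant).  Each valid history arises from exactly one expansion
#' sequence.  Exponential: guarded to tiny cases.
#'
#' @param graph an `events_graph` with k <= 3.
#' @param n history size (n <= 5).
#' @return a list of `gene_history` objects for `graph`'s tree.
#' @export
grow_dtsl_histories <- function(graph, n) {
  stopifnot(inherits(graph, "events_graph"))
  if (graph$k > 3L || n > 5L)
    stop("tree-growing enumeration is limited to k <= 3, n <= 5")
  k <- graph$k
  enode <- function(t, i, children = NULL, open = TRUE)
    list(slice = t, leaf = i, children = children, open = open)
  # expansions of one open leaf
  options_for <- function(nd, can_grow) {
    g <- graph$node_at[nd$slice, nd$leaf]
    out <- list()
    if (nd$slice == k) out <- c(out, list(enode(nd$slice, nd$leaf, list(),
                                                open = FALSE)))
    if (nd$slice < k) {
      out <- c(out, list(enode(nd$slice, nd$leaf,
                               list(enode(nd$slice + 1L, nd$leaf)))))
    }
    if (can_grow) {
      targets <- graph$slices[[nd$slice]] # self => duplication, else transfer
      for (v in targets) for (j in graph$leafset[[v]]) {
        out <- c(out, list(enode(nd$slice, nd$leaf,
                                 list(enode(nd$slice, nd$leaf),
                                      enode(nd$slice, j)))))
      }
    }
    out
  }
  # replace the leftmost open leaf; NULL when the tree is complete
  expand <- function(nd, can_grow) {
    if (nd$open && is.null(nd$children)) return(options_for(nd, can_grow))
    for (ci in seq_along(nd$children)) {
      reps <- expand(nd$children[[ci]], can_grow)
      if (!is.null(reps)) {
        return(lapply(reps, function(r) {
          nd$children[[ci]] <- r
          nd
        }))
      }
    }
    NULL
  }
  count_leaves <- function(nd) {
    if (is.null(nd$children) || length(nd$children) == 0L)
      return(c(open = as.integer(nd$open), done = as.integer(!nd$open)))
    Reduce(`+`, lapply(nd$children, count_leaves))
  }
  strip <- function(nd) list(slice = nd$slice, leaf = nd$leaf,
                             children = lapply(nd$children, strip))
  results <- list()
  stack <- lapply(seq_len(k), function(i) enode(1L, i))
  while (length(stack) > 0L) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    cl <- count_leaves(cur)
    if (cl[["open"]] == 0L) {
      if (cl[["done"]] == n)
        results[[length(results) + 1L]] <-
          decode_history(structure(strip(cur), class = "encoded_history"),
                         graph)
      next
    }
    total <- cl[["open"]] + cl[["done"]]
    reps <- expand(cur, can_grow = total < n)
    for (r in reps) {
      crl <- count_leaves(r)
      if (crl[["open"]] + crl[["done"]] <= n)
        stack[[length(stack) + 1L]] <- r
    }
  }
  results
}
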