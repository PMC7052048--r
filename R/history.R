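# Gene family histories: ordered unary-binary gene trees with an event
# map e (speciation S, duplication D, transfer T, loss L, Extant) and a
# species map s.  A history is stored as a nested list of nodes
# list(event, species, children); the outer node carries class
# "gene_history".  The novel copy created by a duplication or transfer is
# by convention the right child.

hnode <- function(event, species, children = list()) {
  list(event = event, species = species, children = children)
}

as_history <- function(node) structure(node, class = "gene_history")

history_walk <- function(h, fn) {
  rec <- function(node, depth, path) {
    fn(node, depth, path)
    for (i in seq_along(node$children))
      rec(node$children[[i]], depth + 1L, paste0(path, ".", i))
  }
  rec(h, 0L, "1")
  invisible(NULL)
}

#' Size of a history (number of extant genes)
#'
#' @param h a `gene_history`.
#' @return integer count of `Extant` leaves; loss leaves do not count.
#' @export
history_size <- function(h) {
  n <- 0L
  history_walk(h, function(node, depth, path)
    if (node$event == "Extant") n <<- n + 1L)
  n
}

#' @export
print.gene_history <- function(x, ...) {
  cat("Gene family history, size ", history_size(x), "\n", sep = "")
  cat(serialize_history(x), "\n")
  invisible(x)
}

#' Event counts and parsimony score of a history
#'
#' Tallies the evolutionary events of a history.  The (parsimony) score
#' of a history is the number of non-speciation events it invokes:
#' duplications + losses + transfers.
#'
#' @param h a `gene_history`.
#' @return an object of class `event_profile`: a list with integer
#'   components `S`, `D`, `T`, `L`, `Extant` and `score = D + L + T`.
#' @export
event_profile <- function(h) {
  counts <- c(S = 0L, D = 0L, T = 0L, L = 0L, Extant = 0L)
  history_walk(h, function(node, depth, path)
    counts[node$event] <<- counts[node$event] + 1L)
  structure(c(as.list(counts),
              list(score = counts[["D"]] + counts[["L"]] + counts[["T"]])),
            class = "event_profile")
}

#' @export
print.event_profile <- function(x, ...) {
  cat(sprintf("events: S=%d D=%d T=%d L=%d Extant=%d | score=%d\n",
              x$S, x$D, x$T, x$L, x$Extant, x$score))
  invisible(x)
}

## ---- validation ----

#' Check a history against the model constraints
#'
#' Verifies every defining constraint of a history: leaves are extant
#' genes or losses; binary internal nodes are speciations, duplications
#' or transfers; unary internal nodes are pass-through speciations;
#' speciation children map to the species' children; duplication children
#' stay in the same species; a transfer keeps its original copy in the
#' donor species and sends the novel copy to an incomparable species (for
#' ranked models, to the donor's time slice); children of duplications
#' and transfers are never loss leaves (losses only follow speciations,
#' which keeps the history space finite); in the speciation-loss model
#' every binary speciation loses exactly one lineage.
#'
#' @param h a `gene_history`.
#' @param context the `species_tree` or `time_sliced_tree` the history is
#'   embedded in.
#' @param model model name, see [model_spec()].
#' @return a data frame of violations with columns `node` (position path
#'   in the history), `species`, and `problem`; zero rows iff the history
#'   is valid.
#' @export
validate_history <- function(h, context, model) {
  spec <- model_spec(model)
  check_context(context, spec)
  bad <- list()
  note <- function(path, sp, problem)
    bad[[length(bad) + 1L]] <<- data.frame(node = path, species = sp,
                                           problem = problem)
  incomp <- incomparable_ids(context)
  leaf <- lengths(context$children) == 0L
  ids <- stats::setNames(seq_along(context$labels), context$labels)
  if (is.na(ids[h$species]) || ids[[h$species]] != context$root)
    note("1", h$species, "history must start at the species-tree root")
  rec <- function(node, path) {
    sp <- ids[node$species]
    if (is.na(sp)) {
      note(path, node$species, "unknown species label")
      return()
    }
    nc <- length(node$children)
    ev <- node$event
    if (nc == 0L) {
      if (!ev %in% c("Extant", "L"))
        note(path, node$species, "leaf events must be Extant or L")
      if (ev == "Extant" && !leaf[sp])
        note(path, node$species, "extant gene in a non-extant species")
    } else if (nc == 1L) {
      if (ev != "S")
        note(path, node$species, "unary internal nodes must be speciations")
      if (length(context$children[[sp]]) != 1L)
        note(path, node$species, "unary speciation at a non-unary species")
      else {
        want <- context$children[[sp]]
        csp <- ids[node$children[[1L]]$species]
        if (is.na(csp) || csp != want)
          note(path, node$species, "unary speciation child species mismatch")
        if (node$children[[1L]]$event == "L")
          note(path, node$species, "loss under a unary speciation")
      }
    } else if (nc == 2L) {
      lch <- node$children[[1L]]; rch <- node$children[[2L]]
      lsp <- ids[lch$species]; rsp <- ids[rch$species]
      if (!ev %in% c("S", "D", "T"))
        note(path, node$species, "binary events must be S, D or T")
      if (ev == "T" && !spec$transfers)
        note(path, node$species, paste0("transfers not allowed in ",
                                        spec$name))
      if (ev == "S") {
        if (length(context$children[[sp]]) != 2L) {
          note(path, node$species, "speciation at a non-binary species")
        } else {
          want <- context$children[[sp]]
          if (is.na(lsp) || lsp != want[1L])
            note(path, node$species, "speciation left child species mismatch")
          if (is.na(rsp) || rsp != want[2L])
            note(path, node$species, "speciation right child species mismatch")
          nlost <- (lch$event == "L") + (rch$event == "L")
          if (nlost == 2L)
            note(path, node$species, "speciation with both lineages lost")
          if (spec$speciation_loss && nlost != 1L)
            note(path, node$species,
                 "speciation-loss model: exactly one lineage must be lost")
        }
      }
      if (ev %in% c("D", "T") && length(context$children[[sp]]) == 1L &&
          !spec$unary_events)
        note(path, node$species,
             paste0("model ", spec$name,
                    ": unary nodes are pass-throughs only"))
      if (ev == "D") {
        if (is.na(lsp) || is.na(rsp) || lsp != sp || rsp != sp)
          note(path, node$species, "duplication children species mismatch")
        if (lch$event == "L" || rch$event == "L")
          note(path, node$species, "loss directly under a duplication")
      }
      if (ev == "T") {
        if (is.na(lsp) || lsp != sp)
          note(path, node$species, "transfer original copy species mismatch")
        if (is.na(rsp) || !(rsp %in% incomp[[sp]]))
          note(path, node$species,
               "transfer receiver must be incomparable with the donor")
        if (lch$event == "L" || rch$event == "L")
          note(path, node$species, "loss directly under a transfer")
      }
    } else {
      note(path, node$species, "history nodes have at most two children")
    }
    for (i in seq_len(nc)) rec(node$children[[i]], paste0(path, ".", i))
  }
  rec(h, "1")
  if (length(bad) == 0L)
    data.frame(node = character(0), species = character(0),
               problem = character(0))
  else do.call(rbind, bad)
}

## ---- serialization (NHX-style annotated Newick) ----

#' Serialize / parse histories as annotated Newick
#'
#' Histories are written as Newick strings (unary nodes allowed) where
#' every node carries an NHX comment with its event and species, e.g.
#' `"A[&&NHX:event=Extant:species=A];"` for a single extant gene in
#' species A.  `parse_history()` inverts `serialize_history()` exactly.
#'
#' @param h a `gene_history`.
#' @param text an annotated Newick string.
#' @param context the `species_tree` or `time_sliced_tree` whose labels
#'   the species tags must refer to.
#' @return `serialize_history()` a string; `parse_history()` a
#'   `gene_history`.
#' @export
serialize_history <- function(h) {
  rec <- function(node) {
    inner <- if (length(node$children) > 0L)
      paste0("(", paste(vapply(node$children, rec, ""), collapse = ","), ")")
    else ""
    name <- if (length(node$children) == 0L) node$species else ""
    paste0(inner, name,
           "[&&NHX:event=", node$event, ":species=", node$species, "]")
  }
  paste0(rec(h), ";")
}

#' @rdname serialize_history
#' @export
parse_history <- function(text, context) {
  chars <- strsplit(trimws(text), "")[[1L]]
  pos <- 1L
  peek <- function() if (pos <= length(chars)) chars[pos] else ""
  advance <- function() pos <<- pos + 1L
  read_until <- function(stops) {
    out <- character(0)
    while (pos <= length(chars) && !(chars[pos] %in% stops)) {
      out <- c(out, chars[pos]); advance()
    }
    paste(out, collapse = "")
  }
  parse_node <- function() {
    children <- list()
    if (peek() == "(") {
      advance()
      repeat {
        children[[length(children) + 1L]] <- parse_node()
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        stop("malformed history string: expected ',' or ')'")
      }
    }
    read_until(c("[", ",", ")", ";")) # node name (ignored; tag is canonical)
    if (peek() != "[") stop("malformed history string: missing NHX tag")
    tag <- read_until("]")
    advance()
    grab <- function(field) {
      m <- regexpr(paste0("(?<=:", field, "=)[^:]+"), tag, perl = TRUE)
      if (m == -1L) stop("malformed history string: missing ", field, " tag")
      regmatches(tag, m)
    }
    ev <- grab("event"); sp <- grab("species")
    if (!ev %in% c("S", "D", "T", "L", "Extant"))
      stop("malformed history string: bad event '", ev, "'")
    if (!sp %in% context$labels)
      stop("unknown species label '", sp, "' in history string")
    hnode(ev, sp, children)
  }
  node <- parse_node()
  if (peek() != ";") stop("malformed history string: missing ';'")
  as_history(node)
}
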