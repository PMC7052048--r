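# Brute-force enumeration of histories, mirroring the grammar term by
# term.  This is the independent oracle behind the counting DP and the
# uniform sampler: the enumeration recursion is written over the grammar
# alternatives (not the counting tables), and |enumerate| must equal the
# DP count.

#' Exhaustively enumerate all histories of a given size
#'
#' Expands the history grammar for `context` and `model` and returns
#' every history of size `n` exactly once.  The number of histories
#' explodes quickly, so enumeration is guarded: it refuses trees with
#' more than 4 leaves, sizes above 6, and result sets beyond
#' `max_histories`.
#'
#' @param context a `species_tree` or `time_sliced_tree`.
#' @param model model name, see [model_spec()].
#' @param n history size.
#' @param max_histories hard cap on the number of histories returned.
#' @return a list of `gene_history` objects.
#' @examples
#' length(enumerate_histories(make_caterpillar(2), "uDL", 3)) # 34
#' @export
enumerate_histories <- function(context, model, n, max_histories = 2e5) {
  spec <- model_spec(model)
  check_context(context, spec)
  if (context$k > 4L) stop("enumeration is limited to trees with k <= 4")
  if (n < 1L || n > 6L) stop("enumeration is limited to sizes 1..6")
  leaf <- lengths(context$children) == 0L
  incomp <- if (spec$transfers) incomparable_ids(context) else NULL
  memo <- new.env(parent = emptyenv())
  total <- 0L
  pair_up <- function(event, species, ls, rs) {
    out <- vector("list", length(ls) * length(rs))
    i <- 0L
    for (a in ls) for (b in rs) {
      i <- i + 1L
      out[[i]] <- hnode(event, species, list(a, b))
    }
    out
  }
  enum <- function(u, m) {
    key <- paste0(u, ":", m)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- list()
    lab <- context$labels[u]
    ch <- context$children[[u]]
    # leaf atom
    if (leaf[u] && m == 1L) out <- c(out, list(hnode("Extant", lab)))
    # speciation alternatives
    if (length(ch) == 2L) {
      ll <- context$labels[ch[1L]]; rl <- context$labels[ch[2L]]
      if (!spec$speciation_loss && m >= 2L) {
        for (s in seq_len(m - 1L))
          out <- c(out, pair_up("S", lab, enum(ch[1L], s), enum(ch[2L], m - s)))
      }
      out <- c(out, lapply(enum(ch[1L], m), function(a)
        hnode("S", lab, list(a, hnode("L", rl)))))
      out <- c(out, lapply(enum(ch[2L], m), function(b)
        hnode("S", lab, list(hnode("L", ll), b))))
    } else if (length(ch) == 1L) {
      out <- c(out, lapply(enum(ch, m), function(a)
        hnode("S", lab, list(a))))
    }
    # duplication alternatives
    unary <- length(ch) == 1L
    if (m >= 2L && (!unary || spec$unary_events)) {
      for (s in seq_len(m - 1L))
        out <- c(out, pair_up("D", lab, enum(u, s), enum(u, m - s)))
    }
    # transfer alternatives
    if (spec$transfers && m >= 2L && (!unary || spec$unary_events)) {
      for (v in incomp[[u]]) {
        for (s in seq_len(m - 1L))
          out <- c(out, pair_up("T", lab, enum(u, s), enum(v, m - s)))
      }
    }
    total <<- total + length(out)
    if (total > max_histories)
      stop("enumeration cap exceeded (", max_histories, " histories)")
    memo[[key]] <- out
    out
  }
  lapply(enum(context$root, as.integer(n)), as_history)
}
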