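# Dynamic-programming counting of histories.
#
# The grammar of histories translates directly into recurrences over
# tables indexed by (species node u, history size n):
#
#   H[u,n] = S[u,n] + D[u,n] + T[u,n]          (+ [n == 1] if u is a leaf)
#   S[u,n] = sum_m H[ul,m] H[ur,n-m] + H[ul,n] + H[ur,n]   (binary u)
#          = H[uc,n]                                        (unary u)
#   D[u,n] = sum_m H[u,m] H[u,n-m]
#   T[u,n] = sum_m sum_{v incomparable with u} H[u,m] H[v,n-m]
#
# with all splits m in 1..n-1.  Loss leaves are implicit in the two
# single-survivor speciation terms; histories of size 0 do not exist
# (H[u,0] = 0), which is what keeps the space finite.  In the ranked
# models the context is the time-sliced tree (unary nodes pass lineages
# through, transfers stay within a slice); in the speciation-loss model
# rDT-SL the both-children-survive speciation term is dropped.  T terms
# for size n only use sizes < n, so a single pass in increasing n needs
# no fixed point iteration.

MODELS <- c("uDL", "rDL", "uDLT", "rDLT", "rDTSL")

#' Evolutionary model specifications
#'
#' The five supported models: `uDL` and `uDLT` constrain histories by an
#' unranked species tree (duplication + loss, optionally + transfer, with
#' transfer receivers any incomparable species); `rDL` and `rDLT` work on
#' a time-sliced ranked tree (receivers restricted to the donor's time
#' slice, which enforces time consistency); `rDTSL` (written rDT-SL) is
#' the ranked duplication + transfer model in which every speciation is
#' immediately followed by a loss in one of the two lineages.
#'
#' @param model a model name; `"rDT-SL"` is accepted as an alias for
#'   `"rDTSL"`.
#' @return a list with fields `name`, `transfers`, `ranked`,
#'   `speciation_loss`.
#' @export
model_spec <- function(model) {
  if (identical(model, "rDT-SL")) model <- "rDTSL"
  model <- match.arg(model, MODELS)
  list(name = model,
       transfers = model %in% c("uDLT", "rDLT", "rDTSL"),
       ranked = substr(model, 1, 1) == "r",
       speciation_loss = model == "rDTSL",
       # whether duplications (and transfers) may originate at the unary
       # pass-through nodes of a time-sliced tree: yes in the ranked
       # transfer models (every contemporaneous lineage can duplicate or
       # donate), no in rDL, whose unary nodes are pure pass-throughs so
       # that the ranking leaves duplication-loss counts unchanged
       unary_events = model %in% c("rDLT", "rDTSL"))
}

check_context <- function(context, spec) {
  if (spec$ranked && !inherits(context, "time_sliced_tree"))
    stop("model ", spec$name, " needs a time-sliced tree ",
         "(see build_time_slices)")
  if (!spec$ranked && !inherits(context, "species_tree"))
    stop("model ", spec$name, " needs an unranked species_tree")
  invisible(TRUE)
}

#' Build the counting tables H, S, D, T for a model
#'
#' Fills the dynamic-programming tables counting the histories of every
#' size up to `n_max` for every subtree of the species tree, as exact big
#' integers.  `history_count()` reads off the number of histories of a
#' given size at the root; `growth_estimate()` forms the ratio of
#' consecutive counts, an estimator of the exponential growth factor
#' 1/rho of the model; `sample_history()` uses the tables to draw
#' uniform random histories.
#'
#' @param context a `species_tree` (models `uDL`, `uDLT`) or a
#'   `time_sliced_tree` (models `rDL`, `rDLT`, `rDTSL`).
#' @param model a model name, see [model_spec()].
#' @param n_max largest history size to tabulate (>= 1).
#' @return an object of class `count_tables`.
#' @examples
#' tb <- build_count_tables(make_caterpillar(2), "uDL", 10)
#' history_count(tb, 10) # 35066384
#' @export
build_count_tables <- function(context, model, n_max) {
  spec <- model_spec(model)
  check_context(context, spec)
  stopifnot(n_max >= 1, n_max == floor(n_max))
  n_max <- as.integer(n_max)
  nn <- length(context$labels)
  ord <- post_order(context)
  leaf <- lengths(context$children) == 0L
  incomp <- if (spec$transfers) incomparable_ids(context) else NULL
  newtab <- function() lapply(seq_len(nn), function(i) vector("list", n_max))
  H <- newtab(); S <- newtab(); D <- newtab(); Tt <- newtab()
  Ccache <- if (spec$transfers) lapply(seq_len(nn), function(i)
    vector("list", n_max)) else NULL
  for (n in seq_len(n_max)) {
    for (u in ord) {
      ch <- context$children[[u]]
      # speciation term
      s <- 0
      if (length(ch) == 2L) {
        ul <- ch[1L]; ur <- ch[2L]
        if (!spec$speciation_loss && n >= 2L) {
          for (m in seq_len(n - 1L))
            s <- big_add(s, big_mul(H[[ul]][[m]], H[[ur]][[n - m]]))
        }
        s <- big_add(s, big_add(H[[ul]][[n]], H[[ur]][[n]]))
      } else if (length(ch) == 1L) {
        s <- H[[ch]][[n]]
      }
      # duplication term
      unary <- length(ch) == 1L
      d <- 0
      if (n >= 2L && (!unary || spec$unary_events)) {
        for (m in seq_len(n - 1L))
          d <- big_add(d, big_mul(H[[u]][[m]], H[[u]][[n - m]]))
      }
      # transfer term
      tt <- 0
      if (spec$transfers && length(incomp[[u]]) > 0L && n >= 2L &&
          (!unary || spec$unary_events)) {
        j <- n - 1L # extend the receiver-sum cache to the new size
        Ccache[[u]][[j]] <- big_sum(lapply(incomp[[u]],
                                           function(v) H[[v]][[j]]))
        for (m in seq_len(n - 1L))
          tt <- big_add(tt, big_mul(H[[u]][[m]], Ccache[[u]][[n - m]]))
      }
      h <- big_add(big_add(s, d), tt)
      if (leaf[u] && n == 1L) h <- big_add(h, 1)
      S[[u]][[n]] <- s; D[[u]][[n]] <- d; Tt[[u]][[n]] <- tt
      H[[u]][[n]] <- h
    }
  }
  logH <- matrix(-Inf, nn, n_max)
  for (u in seq_len(nn)) for (n in seq_len(n_max))
    logH[u, n] <- big_log(H[[u]][[n]])
  structure(list(model = spec, context = context, n_max = n_max,
                 H = H, S = S, D = D, T = Tt,
                 logH = logH, incomp = incomp, leaf = leaf),
            class = "count_tables")
}

#' @export
print.count_tables <- function(x, ...) {
  cat("History counting tables: model ", x$model$name,
      ", k = ", x$context$k, ", n_max = ", x$n_max, "\n", sep = "")
  n_show <- min(x$n_max, 8L)
  cat("  counts at root, n = 1..", n_show, ": ",
      paste(vapply(seq_len(n_show),
                   function(n) big_to_string(x$H[[x$context$root]][[n]]), ""),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of histories of a given size
#'
#' @param tables a `count_tables` object from [build_count_tables()].
#' @param n history size (number of extant genes), `1 <= n <= n_max`.
#' @return a [bigint][as.bigint]: the exact number of histories of size
#'   `n` for the whole species tree.
#' @export
history_count <- function(tables, n) {
  stopifnot(inherits(tables, "count_tables"))
  if (n < 1 || n > tables$n_max) stop("n must be in 1..n_max")
  new_bigint(tables$H[[tables$context$root]][[n]])
}

#' All tabulated history counts as decimal strings
#'
#' @param tables a `count_tables` object.
#' @return a character vector of length `n_max`; element n is the exact
#'   decimal count of histories of size n.
#' @export
history_counts <- function(tables) {
  stopifnot(inherits(tables, "count_tables"))
  vapply(seq_len(tables$n_max),
         function(n) big_to_string(tables$H[[tables$context$root]][[n]]), "")
}

#' Growth-factor estimate from consecutive counts
#'
#' The ratio h(n)/h(n-1) of consecutive history counts converges to the
#' exponential growth factor 1/rho of the model (the counts behave like
#' gamma rho^-n n^-3/2, so the ratio underestimates 1/rho by a factor
#' (1 - 1/n)^... ~ 1 - 3/(2n)).  This is the workhorse estimator for the
#' models whose generating functions have no tractable closed form.
#'
#' @param tables a `count_tables` object.
#' @param n size at the numerator (`2 <= n <= n_max`).
#' @return a double, `h(n)/h(n-1)`.
#' @export
growth_estimate <- function(tables, n) {
  stopifnot(inherits(tables, "count_tables"))
  if (n < 2 || n > tables$n_max) stop("n must be in 2..n_max")
  r <- tables$context$root
  if (big_is_zero(tables$H[[r]][[n - 1L]]))
    stop("no histories of size ", n - 1L, ": ratio undefined")
  big_ratio(tables$H[[r]][[n]], tables$H[[r]][[n - 1L]])
}
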