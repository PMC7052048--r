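# Uniform random generation of histories by the recursive method: walk
# the grammar from the root state (species root, size n), choosing each
# alternative with probability proportional to the number of histories it
# contributes, then recursing on the chosen sub-states.  The counting
# tables are exact big integers; the choice weights are evaluated in log
# space (double precision), whose ~1e-13 relative rounding is far below
# anything detectable at realistic sample sizes.

#' Draw a history of size n uniformly at random
#'
#' Uses the recursive method on the counting tables: at every state
#' (species node u, size m) an alternative — extant leaf, speciation with
#' a given size split or a lost lineage, duplication split, or transfer
#' (receiver, split) — is chosen with probability proportional to the
#' number of histories it generates, which makes the output exactly
#' uniform over all histories of size `n`.
#'
#' @param tables a `count_tables` object from [build_count_tables()].
#' @param n history size, `1 <= n <= n_max`.
#' @param seed integer seed; the same `(tables, n, seed)` reproduces the
#'   same history.
#' @return a `gene_history` of size `n`.
#' @examples
#' tb <- build_count_tables(make_caterpillar(2), "uDL", 5)
#' sample_history(tb, 3, seed = 1)
#' @export
sample_history <- function(tables, n, seed = NULL) {
  stopifnot(inherits(tables, "count_tables"))
  if (n < 1 || n > tables$n_max) stop("n must be in 1..n_max")
  ctx <- tables$context
  if (big_is_zero(tables$H[[ctx$root]][[n]]))
    stop("no histories of size ", n, " exist for this tree and model")
  if (!is.null(seed)) set.seed(seed)
  spec <- tables$model
  logH <- tables$logH
  leaf <- tables$leaf
  incomp <- tables$incomp
  draw <- function(u, m) {
    ch <- ctx$children[[u]]
    lab <- ctx$labels[u]
    type <- character(0); lw <- numeric(0)
    split <- integer(0); recv <- integer(0)
    add <- function(ty, w, sp = 0L, rv = 0L) {
      kk <- length(w)
      type <<- c(type, rep(ty, kk)); lw <<- c(lw, w)
      split <<- c(split, if (length(sp) == kk) sp else rep(sp, kk))
      recv <<- c(recv, rep(rv, kk))
    }
    if (leaf[u] && m == 1L) add("extant", 0)
    if (length(ch) == 2L) {
      if (!spec$speciation_loss && m >= 2L) {
        mm <- seq_len(m - 1L)
        add("s_both", logH[ch[1L], mm] + logH[ch[2L], m - mm], sp = mm)
      }
      add("s_lossr", logH[ch[1L], m])
      add("s_lossl", logH[ch[2L], m])
    } else if (length(ch) == 1L) {
      add("s_unary", logH[ch, m])
    }
    if (m >= 2L && (length(ch) != 1L || spec$unary_events)) {
      mm <- seq_len(m - 1L)
      add("dup", logH[u, mm] + logH[u, m - mm], sp = mm)
      if (spec$transfers) {
        for (v in incomp[[u]])
          add("transfer", logH[u, mm] + logH[v, m - mm], sp = mm, rv = v)
      }
    }
    top <- max(lw)
    if (top == -Inf) stop("internal error: zero-mass state (", lab, ", ",
                          m, ")")
    i <- sample.int(length(lw), 1L, prob = exp(lw - top))
    s <- split[i]
    switch(type[i],
      extant = hnode("Extant", lab),
      s_both = hnode("S", lab, list(draw(ch[1L], s), draw(ch[2L], m - s))),
      s_lossr = hnode("S", lab, list(draw(ch[1L], m),
                                     hnode("L", ctx$labels[ch[2L]]))),
      s_lossl = hnode("S", lab, list(hnode("L", ctx$labels[ch[1L]]),
                                     draw(ch[2L], m))),
      s_unary = hnode("S", lab, list(draw(ch, m))),
      dup = hnode("D", lab, list(draw(u, s), draw(u, m - s))),
      transfer = hnode("T", lab, list(draw(u, s), draw(recv[i], m - s)))
    )
  }
  as_history(draw(ctx$root, as.integer(n)))
}

#' Sample many histories and tabulate their event profiles
#'
#' Convenience wrapper drawing `num` independent uniform histories and
#' returning one row of event counts per history.
#'
#' @param tables a `count_tables` object.
#' @param n history size.
#' @param num number of histories.
#' @param seed integer seed for the whole batch.
#' @return a data frame with columns `S`, `D`, `T`, `L`, `Extant`,
#'   `score`.
#' @export
sample_profiles <- function(tables, n, num, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", num)
  for (i in seq_len(num)) {
    p <- event_profile(sample_history(tables, n))
    rows[[i]] <- data.frame(S = p$S, D = p$D, T = p$T, L = p$L,
                            Extant = p$Extant, score = p$score)
  }
  do.call(rbind, rows)
}
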