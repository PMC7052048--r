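# High-level drivers used by the command-line front end and by the
# reduced-scale reproductions of the survey experiments: growth-factor
# surveys over random species trees, the rDT-SL invariance check, and
# score/profile distributions of random histories.

resolve_tree <- function(tree = NULL, family = NULL, k = NULL, h = NULL,
                         seed = NULL) {
  if (!is.null(tree)) {
    if (inherits(tree, "species_tree")) return(tree)
    return(parse_newick(tree, file = file.exists(tree)))
  }
  switch(match.arg(family, c("caterpillar", "complete-binary", "balanced",
                             "random")),
         "caterpillar" = make_caterpillar(k),
         "complete-binary" = make_complete_binary(h),
         "balanced" = make_balanced(k),
         "random" = random_topology(k, seed))
}

prepare_context <- function(tree, model, rank_seed = 1L) {
  spec <- model_spec(model)
  if (!spec$ranked) return(tree)
  build_time_slices(tree, random_ranking(tree, seed = rank_seed))
}

#' Count histories: driver
#'
#' Builds the counting tables for a tree and model and returns the count
#' sequence in a JSON-ready structure (decimal strings: the counts
#' overflow doubles quickly).
#'
#' @param tree a `species_tree`, a Newick string, or a file path; or
#'   `NULL` to use `family`.
#' @param family one of `"caterpillar"`, `"complete-binary"`,
#'   `"balanced"`, `"random"` (used when `tree` is `NULL`).
#' @param k,h family size parameters.
#' @param model model name, see [model_spec()].
#' @param n_max largest size to count.
#' @param seed seed for the random family and, in ranked models, the
#'   ranking.
#' @return a list `(model, k, counts)` where `counts` is a named list of
#'   decimal strings indexed by size.
#' @export
run_count <- function(tree = NULL, family = NULL, k = NULL, h = NULL,
                      model = "uDL", n_max = 10, seed = 1) {
  tr <- resolve_tree(tree, family, k, h, seed)
  ctx <- prepare_context(tr, model, rank_seed = seed)
  tb <- build_count_tables(ctx, model, n_max)
  counts <- as.list(history_counts(tb))
  names(counts) <- as.character(seq_len(n_max))
  list(model = model_spec(model)$name, k = tr$k, seed = seed,
       counts = counts)
}

#' Growth-factor estimate: driver
#'
#' Computes the finite-size growth estimate h(n)/h(n-1) and, in the uDL
#' model, the exact growth factor 1/rho from the singularity solver.
#'
#' @inheritParams run_count
#' @param n size at the numerator of the estimate.
#' @return a list `(model, k, n, estimate, exact)`; `exact` is `NA`
#'   outside the uDL model.
#' @export
run_growth <- function(tree = NULL, family = NULL, k = NULL, h = NULL,
                       model = "uDL", n = 50, seed = 1) {
  tr <- resolve_tree(tree, family, k, h, seed)
  ctx <- prepare_context(tr, model, rank_seed = seed)
  tb <- build_count_tables(ctx, model, n)
  est <- growth_estimate(tb, n)
  exact <- if (model_spec(model)$name == "uDL")
    dominant_singularity(tr)$growth else NA_real_
  list(model = model_spec(model)$name, k = tr$k, n = n,
       estimate = est, exact = exact)
}

#' uDL asymptotics: driver
#'
#' @inheritParams run_count
#' @return a list `(k, rho, growth, gamma)`.
#' @export
run_asymptotics <- function(tree = NULL, family = NULL, k = NULL, h = NULL,
                            seed = 1) {
  tr <- resolve_tree(tree, family, k, h, seed)
  res <- dl_asymptotics(tr)
  list(k = tr$k, rho = res$rho, growth = res$growth, gamma = res$gamma)
}

#' Sample histories: driver
#'
#' @inheritParams run_count
#' @param n history size.
#' @param num number of histories to draw.
#' @return a list with `histories` (annotated-Newick strings) and
#'   `profiles` (data frame of event counts, one row per history).
#' @export
run_sample <- function(tree = NULL, family = NULL, k = NULL, h = NULL,
                       model = "uDL", n = 10, num = 10, seed = 1) {
  tr <- resolve_tree(tree, family, k, h, seed)
  ctx <- prepare_context(tr, model, rank_seed = seed)
  tb <- build_count_tables(ctx, model, n)
  set.seed(seed)
  hs <- replicate(num, sample_history(tb, n), simplify = FALSE)
  profs <- do.call(rbind, lapply(hs, function(hh) {
    p <- event_profile(hh)
    data.frame(S = p$S, D = p$D, T = p$T, L = p$L, Extant = p$Extant,
               score = p$score)
  }))
  list(model = model_spec(model)$name, k = tr$k, n = n, seed = seed,
       histories = vapply(hs, serialize_history, ""),
       profiles = profs)
}

#' Species-tree independence of rDT-SL counts: driver
#'
#' Builds the rDT-SL count vector up to `n_max` for every (topology,
#' ranking) pair with `k` leaves and checks they are all identical.
#'
#' @param k number of leaves (k <= 6 to keep the enumeration of pairs
#'   manageable).
#' @param n_max largest size to compare.
#' @return a list with `k`, `n_max`, `n_pairs`, `pass` (logical), and
#'   `counts` (the common count vector, decimal strings).
#' @export
run_dtsl_check <- function(k, n_max = 10) {
  stopifnot(k >= 2, k <= 6)
  vecs <- list()
  for (tr in enumerate_topologies(k)) {
    for (rk in enumerate_rankings(tr)) {
      tb <- count_dtsl(build_time_slices(tr, rk), n_max)
      vecs[[length(vecs) + 1L]] <- history_counts(tb)
    }
  }
  common <- vecs[[1L]]
  pass <- all(vapply(vecs, identical, TRUE, y = common))
  list(k = k, n_max = n_max, n_pairs = length(vecs), pass = pass,
       counts = common)
}

#' Score distributions of random histories: driver
#'
#' Reduced-scale reproduction of the parsimony-score survey: draws
#' uniform histories of size `n` on one random species tree of size `k`
#' under both the uDL and uDLT models and tabulates their event
#' profiles.  Including transfers shifts the score distribution down.
#'
#' @param k species-tree size.
#' @param n history size.
#' @param num histories per model.
#' @param seed integer seed (tree choice and sampling).
#' @return a data frame with columns `model`, `S`, `D`, `T`, `L`,
#'   `Extant`, `score`.
#' @export
run_score_experiment <- function(k = 16, n = 30, num = 1000, seed = 1) {
  tr <- random_topology(k, seed = seed)
  out <- list()
  for (model in c("uDL", "uDLT")) {
    tb <- build_count_tables(tr, model, n)
    set.seed(seed + 1L)
    out[[model]] <- cbind(model = model,
                          sample_profiles(tb, n, num))
  }
  do.call(rbind, out)
}

#' Box-plot of history scores per model
#'
#' @param profiles a data frame from [run_score_experiment()].
#' @param ... passed to [graphics::boxplot()].
#' @export
plot_score_profiles <- function(profiles, ...) {
  graphics::boxplot(score ~ model, data = profiles,
                    ylab = "score (D + L + T)", ...)
  invisible(NULL)
}
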