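# Asymptotics of duplication-loss history counts via singularity
# analysis.  For the unranked DL model the generating function of every
# subtree satisfies H_u = B(H_ul H_ur + H_ul + H_ur) with
# B(z) = (1 - sqrt(1-4z))/2, so H_u(z) = (1 - sqrt(R_u(z)))/2 where the
# nested radicands obey
#
#   R_u = -4 + 3 sqrt(R_ul) + 3 sqrt(R_ur) - sqrt(R_ul R_ur),  R_leaf = 1-4z.
#
# R_u(0) = 1, R_u decreases on [0, rho_u], and the dominant singularity
# rho_u of H_u is the unique zero of R_u, a simple root below every
# child's singularity.  Around rho the square-root singularity gives
# counts ~ gamma rho^-n n^(-3/2) with gamma = sqrt(-rho R'(rho))/(4 sqrt(pi)).

#' Evaluate the nested radicand R_u(z) of a subtree
#'
#' @param tree a `species_tree`.
#' @param z evaluation point (scalar).
#' @param node label of the subtree root; default the tree root.
#' @return R_u(z); `R_u(0) = 1` for every node.  Signals an error if an
#'   inner (child) radicand is negative, i.e. `z` lies beyond a child's
#'   singularity.
#' @export
radicand_value <- function(tree, z, node = NULL) {
  stopifnot(inherits(tree, "species_tree"), length(z) == 1L)
  u <- if (is.null(node)) tree$root else node_id(tree, node)
  rec <- function(i) {
    ch <- tree$children[[i]]
    if (length(ch) == 0L) return(1 - 4 * z)
    rl <- rec(ch[1L]); rr <- rec(ch[2L])
    if (rl < 0 || rr < 0)
      stop("radicand out of domain: z = ", z,
           " lies beyond a child singularity")
    -4 + 3 * sqrt(rl) + 3 * sqrt(rr) - sqrt(rl * rr)
  }
  rec(u)
}

#' Dominant singularity of the uDL history generating function
#'
#' Locates, for every subtree bottom-up, the unique zero of the nested
#' radicand on (0, min of the children's singularities] by bracketed
#' bisection (the radicand decreases from 1 at z = 0 and is negative at
#' the children's singularity, so the bracket is guaranteed).  The
#' reciprocal 1/rho is the exponential growth factor of the number of
#' histories.
#'
#' @param tree a `species_tree`.
#' @param tol bisection tolerance on |R(rho)|.
#' @return an object of class `singularity_result`: a list with `rho`,
#'   `growth = 1/rho`, `rho_by_node` (named, in post-order), and `gamma`
#'   (`NA` until [asymptotic_constant()] fills it in via
#'   [dl_asymptotics()]).
#' @examples
#' dominant_singularity(make_caterpillar(3))$growth # about 15.72
#' @export
dominant_singularity <- function(tree, tol = 1e-14) {
  stopifnot(inherits(tree, "species_tree"), tol > 0)
  n <- n_nodes(tree)
  rho <- rep(NA_real_, n)
  rad <- function(i, z) { # radicand of node i, children's rho known finite
    ch <- tree$children[[i]]
    if (length(ch) == 0L) return(1 - 4 * z)
    rl <- rad(ch[1L], z); rr <- rad(ch[2L], z)
    -4 + 3 * sqrt(max(rl, 0)) + 3 * sqrt(max(rr, 0)) -
      sqrt(max(rl, 0) * max(rr, 0))
  }
  for (i in post_order(tree)) {
    ch <- tree$children[[i]]
    if (length(ch) == 0L) { rho[i] <- 0.25; next }
    lo <- 0; hi <- min(rho[ch])
    for (it in seq_len(200L)) {
      mid <- (lo + hi) / 2
      fm <- rad(i, mid)
      if (abs(fm) <= tol && (hi - lo) <= 1e-15 * max(hi, 1)) break
      if (fm > 0) lo <- mid else hi <- mid
    }
    rho[i] <- (lo + hi) / 2
  }
  ord <- post_order(tree)
  structure(list(rho = rho[tree$root], growth = 1 / rho[tree$root],
                 gamma = NA_real_,
                 rho_by_node = stats::setNames(rho[ord], tree$labels[ord])),
            class = "singularity_result")
}

#' @export
print.singularity_result <- function(x, ...) {
  cat(sprintf("dominant singularity rho = %.12g (growth %.2f)\n",
              x$rho, x$growth))
  if (!is.na(x$gamma)) cat(sprintf("leading constant gamma = %.4f\n", x$gamma))
  invisible(x)
}

#' Leading asymptotic constant for a uDL history count
#'
#' Computes the constant gamma in counts ~ gamma rho^-n n^(-3/2) from
#' the local expansion of the root radicand at its simple zero:
#' gamma = sqrt(-rho R'(rho)) / (4 sqrt(pi)), with R'(rho) estimated by
#' central finite differences (step 1e-6 rho).  On caterpillar and
#' complete binary trees it agrees with the closed forms
#' [caterpillar_constant()] and [complete_binary_constant()].
#'
#' @param tree a `species_tree`.
#' @param rho the dominant singularity, from [dominant_singularity()].
#' @return the constant gamma (> 0).
#' @export
asymptotic_constant <- function(tree, rho) {
  stopifnot(inherits(tree, "species_tree"), rho > 0, rho <= 0.25)
  h <- 1e-6 * rho
  f <- function(z) { # children radicands stay positive near rho
    rec <- function(i) {
      ch <- tree$children[[i]]
      if (length(ch) == 0L) return(1 - 4 * z)
      rl <- rec(ch[1L]); rr <- rec(ch[2L])
      -4 + 3 * sqrt(rl) + 3 * sqrt(rr) - sqrt(rl * rr)
    }
    rec(tree$root)
  }
  rp <- (f(rho + h) - f(rho - h)) / (2 * h)
  if (!is.finite(rp) || rp >= 0)
    warning("unstable derivative estimate at the singularity")
  sqrt(-rho * rp) / (4 * sqrt(pi))
}

#' Growth factor and leading constant of the uDL asymptotics
#'
#' Convenience wrapper running [dominant_singularity()] and
#' [asymptotic_constant()].
#'
#' @inheritParams dominant_singularity
#' @return a `singularity_result` with `gamma` filled in.
#' @export
dl_asymptotics <- function(tree, tol = 1e-14) {
  res <- dominant_singularity(tree, tol)
  res$gamma <- asymptotic_constant(tree, res$rho)
  res
}

#' First-order asymptotic approximation of a history count
#'
#' Evaluates gamma rho^-n n^(-3/2), the leading term of the number of
#' uDL histories of size n.
#'
#' @param res a `singularity_result` (or any list with `rho` and
#'   `gamma`).
#' @param n history size.
#' @param log return the natural log of the approximation (useful when
#'   the count overflows double precision).
#' @return a double.
#' @export
asymptotic_count <- function(res, n, log = FALSE) {
  stopifnot(n >= 1)
  lv <- log(res$gamma) - n * base::log(res$rho) - 1.5 * base::log(n)
  if (log) lv else exp(lv)
}

## ---- closed forms: caterpillar trees ----

# s_k(X): s_1 = 0, s_k = (3X - 4 - s_{k-1}^2)/(X - 3); the radicand
# substitution X = sqrt(1-4z) turns the caterpillar radicand chain into
# the fixed point problem s_k(X) = X.
caterpillar_s <- function(k, X) {
  s <- 0
  if (k >= 2) for (j in 2:k) s <- (3 * X - 4 - s^2) / (X - 3)
  s
}

#' Caterpillar asymptotics: singularity and constant in closed form
#'
#' For the caterpillar tree CT_k the dominant singularity is
#' lambda_k = (1 - X_k^2)/4 where X_k is the minimal positive solution of
#' the fixed point equation s_k(X) = X, with s_1 = 0 and
#' s_k = (3X - 4 - s_{k-1}^2)/(X - 3).  `caterpillar_constant()` returns
#' the leading constant alpha_k, evaluated through the derivative
#' recurrence of the radicand chain at X_k.
#'
#' @param k caterpillar size (k >= 1).
#' @return `caterpillar_singularity()`: a list of class
#'   `caterpillar_asymptotics` with `k`, `X`, `lambda`, and
#'   `growth = 1/lambda`.  `caterpillar_constant()`: the constant
#'   alpha_k > 0.
#' @examples
#' caterpillar_singularity(2)$growth # 9.61 (X_2 = 3 - sqrt(5))
#' @export
caterpillar_singularity <- function(k) {
  stopifnot(k >= 1, k == floor(k), k <= 64)
  if (k == 1) {
    X <- 0
  } else {
    g <- function(X) caterpillar_s(k, X) - X
    grid <- seq(1e-9, 1 - 1e-9, length.out = 4001L)
    vals <- vapply(grid, g, 0)
    sw <- which(vals[-1L] * vals[-length(vals)] <= 0)[1L]
    if (is.na(sw)) stop("failed to bracket the fixed point for k = ", k)
    X <- stats::uniroot(g, c(grid[sw], grid[sw + 1L]), tol = 1e-15)$root
  }
  lambda <- (1 - X^2) / 4
  structure(list(k = k, X = X, lambda = lambda, growth = 1 / lambda),
            class = "caterpillar_asymptotics")
}

#' @rdname caterpillar_singularity
#' @export
caterpillar_constant <- function(k) {
  stopifnot(k >= 1, k == floor(k), k <= 64)
  if (k == 1) return(1 / (4 * sqrt(pi)))
  cs <- caterpillar_singularity(k)
  X <- cs$X
  svals <- numeric(k) # svals[j] = s_j(X_k)
  for (j in 2:k) svals[j] <- (3 * X - 4 - svals[j - 1]^2) / (X - 3)
  # derivative chain of the radicands P~_i at X_k, using
  # sqrt(P~_i(X_k)) = s_{k-i+1}(X_k)
  d <- 2 * X
  for (i in 2:k) {
    p_prev <- svals[k - i + 2L]
    d <- (3 - p_prev) + (3 - X) / (2 * p_prev) * d
  }
  sqrt(cs$lambda * d / (8 * pi * X))
}

## ---- closed forms: complete binary trees ----

#' Complete binary tree asymptotics in closed form
#'
#' For CB_h the radicand recurrence has z-independent coefficients, so
#' the singularity iterates explicitly: mu_h = (1 - q_h)/4 with q_0 = 0
#' and q_(h+1) = (3 - sqrt(5 - q_h))^2.  The leading constant beta_h
#' follows from the derivative recurrence
#' Q_h' = (3/sqrt(Q_(h-1)) - 1) Q_(h-1)', giving
#' beta_h = sqrt(mu_h/(4 pi) * prod_(i=1..h) (3/sqrt(q_i) - 1)).
#'
#' @param h height of the complete binary tree (h >= 0, 2^h leaves).
#' @return `complete_binary_singularity()`: a list of class
#'   `complete_binary_asymptotics` with `h`, `q` (the value q_h), `qs`
#'   (q_1..q_h), `mu`, and `growth = 1/mu`.
#'   `complete_binary_constant()`: the constant beta_h > 0.
#' @examples
#' complete_binary_singularity(2)$growth # 20.75
#' @export
complete_binary_singularity <- function(h) {
  stopifnot(h >= 0, h == floor(h))
  q <- 0
  qs <- numeric(0)
  if (h > 0) for (i in seq_len(h)) {
    q <- (3 - sqrt(5 - q))^2
    qs[i] <- q
  }
  mu <- (1 - q) / 4
  structure(list(h = h, q = q, qs = qs, mu = mu, growth = 1 / mu),
            class = "complete_binary_asymptotics")
}

#' @rdname complete_binary_singularity
#' @export
complete_binary_constant <- function(h) {
  cb <- complete_binary_singularity(h)
  sqrt(cb$mu / (4 * pi) * prod(3 / sqrt(cb$qs) - 1))
}
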