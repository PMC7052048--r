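test_that("radicands are 1 at the origin and vanish at the singularity", {
  tr <- random_topology(7, seed = 3)
  for (lab in tr$labels)
    expect_equal(radicand_value(tr, 0, node = lab), 1, tolerance = 1e-12)
  # cherry: closed-form singularity lambda_2 = (1 - (3 - sqrt(5))^2)/4
  lambda2 <- (1 - (3 - sqrt(5))^2) / 4
  expect_lt(abs(radicand_value(make_caterpillar(2), lambda2)), 1e-6)
  expect_equal(radicand_value(make_caterpillar(1), 0.1), 1 - 0.4)
  expect_error(radicand_value(make_caterpillar(2), 0.26), "out of domain")
})

test_that("caterpillar closed forms reproduce the published table", {
  for (i in seq_len(nrow(TABLE2_CAT))) {
    k <- TABLE2_CAT$k[i]
    cs <- caterpillar_singularity(k)
    expect_printed(cs$growth, TABLE2_CAT$growth[i], 2)
    expect_printed(caterpillar_constant(k), TABLE2_CAT$alpha[i], 4)
  }
  expect_equal(caterpillar_singularity(1)$X, 0)
  expect_equal(caterpillar_singularity(1)$lambda, 0.25)
  expect_equal(caterpillar_singularity(2)$X, 3 - sqrt(5), tolerance = 1e-12)
})

test_that("complete binary closed forms reproduce the published table", {
  for (i in seq_len(nrow(TABLE2_CB))) {
    h <- TABLE2_CB$h[i]
    cb <- complete_binary_singularity(h)
    expect_printed(cb$growth, TABLE2_CB$growth[i], 2)
    expect_printed(complete_binary_constant(h), TABLE2_CB$beta[i], 4)
  }
  expect_equal(complete_binary_singularity(0)$q, 0)
  expect_equal(complete_binary_singularity(0)$mu, 0.25)
  # q_h increases, mu_h decreases
  mus <- vapply(0:6, function(h) complete_binary_singularity(h)$mu, 0)
  expect_true(all(diff(mus) < 0))
})

test_that("the same tree gives the same asymptotics by both closed forms", {
  expect_equal(caterpillar_singularity(2)$lambda,
               complete_binary_singularity(1)$mu, tolerance = 1e-12)
  expect_equal(caterpillar_constant(2), complete_binary_constant(1),
               tolerance = 1e-12)
})

test_that("the generic singularity solver agrees with the closed forms", {
  for (k in 1:16)
    expect_lt(abs(dominant_singularity(make_caterpillar(k))$rho -
                  caterpillar_singularity(k)$lambda), 1e-9)
  for (h in 0:4)
    expect_lt(abs(dominant_singularity(make_complete_binary(h))$rho -
                  complete_binary_singularity(h)$mu), 1e-9)
  expect_equal(dominant_singularity(make_caterpillar(1))$rho, 0.25,
               tolerance = 1e-12)
})

test_that("the generic constant agrees with the closed forms", {
  for (k in c(1, 2, 5, 10, 16)) {
    tr <- make_caterpillar(k)
    g <- asymptotic_constant(tr, dominant_singularity(tr)$rho)
    expect_equal(g, caterpillar_constant(k), tolerance = 1e-6)
  }
  for (h in 0:4) {
    tr <- make_complete_binary(h)
    g <- asymptotic_constant(tr, dominant_singularity(tr)$rho)
    expect_equal(g, complete_binary_constant(h), tolerance = 1e-6)
  }
  expect_equal(asymptotic_constant(make_caterpillar(1), 0.25),
               1 / (4 * sqrt(pi)), tolerance = 1e-9)
})

test_that("singularities shrink strictly from leaves to the root", {
  for (s in 1:20) {
    tr <- random_topology(sample(3:8, 1), seed = 100 + s)
    rho <- dominant_singularity(tr)$rho_by_node
    for (i in seq_along(tr$labels)) {
      p <- tr$parent[i]
      if (!is.na(p))
        expect_lt(rho[[tr$labels[p]]], rho[[tr$labels[i]]])
    }
  }
})

test_that("first-order asymptotics track the exact counts", {
  # single species: compare against the exact Catalan count
  leaf_res <- dl_asymptotics(make_caterpillar(1))
  expect_equal(asymptotic_count(leaf_res, 20),
               as.numeric(big_catalan(19)), tolerance = 0.05)
  # cherry at n = 10: first-order approximation within 20%
  ch_res <- dl_asymptotics(make_caterpillar(2))
  expect_equal(asymptotic_count(ch_res, 10), 35066384, tolerance = 0.2)
  expect_equal(asymptotic_count(list(rho = 1, gamma = 1), 1), 1)
  # relative error decays like 1/n
  for (k in 1:4) {
    tr <- make_caterpillar(k)
    res <- dl_asymptotics(tr)
    tb <- build_count_tables(tr, "uDL", 60)
    err <- function(n) abs(asymptotic_count(res, n, log = TRUE) -
                             log(history_count(tb, n)))
    expect_lt(err(60), err(30))
  }
})

test_that("log-scale evaluation survives huge sizes", {
  res <- dl_asymptotics(make_caterpillar(16))
  lv <- asymptotic_count(res, 500, log = TRUE)
  expect_true(is.finite(lv))
  expect_gt(lv, 500 * log(170)) # growth factor is about 174
})
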