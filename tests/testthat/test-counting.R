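test_that("caterpillar uDL counts match the published sequences", {
  for (k in 1:5) {
    seq_k <- TABLE3[[as.character(k)]]
    tb <- build_count_tables(make_caterpillar(k), "uDL", length(seq_k))
    expect_identical(history_counts(tb), seq_k)
  }
})

test_that("complete binary uDL counts match the published sequences", {
  for (h in 0:4) {
    seq_h <- TABLE4[[as.character(h)]]
    tb <- build_count_tables(make_complete_binary(h), "uDL", length(seq_h))
    expect_identical(history_counts(tb), seq_h)
  }
})

test_that("single-species counts are Catalan numbers (uDL and uDLT)", {
  leaf <- make_caterpillar(1)
  for (model in c("uDL", "uDLT")) {
    tb <- build_count_tables(leaf, model, 14)
    for (n in 1:14)
      expect_true(history_count(tb, n) == big_catalan(n - 1))
  }
})

test_that("enumeration oracle equals the DP count (k <= 3, all models, n <= 4)", {
  for (k in 1:3) {
    tr <- make_caterpillar(k) # the only shape for k <= 3
    for (model in c("uDL", "uDLT")) {
      tb <- build_count_tables(tr, model, 4)
      for (n in 1:4)
        expect_equal(length(enumerate_histories(tr, model, n)),
                     as.numeric(history_count(tb, n)),
                     info = paste(model, "k", k, "n", n))
    }
    for (rk in enumerate_rankings(tr)) {
      st <- build_time_slices(tr, rk)
      for (model in c("rDL", "rDLT", "rDTSL")) {
        tb <- build_count_tables(st, model, 4)
        for (n in 1:4) {
          hs <- enumerate_histories(st, model, n)
          expect_equal(length(hs), as.numeric(history_count(tb, n)),
                       info = paste(model, "k", k, "n", n))
          expect_equal(anyDuplicated(vapply(hs, history_key, "")), 0)
        }
      }
    }
  }
})

test_that("enumerated histories validate, and frozen spot values hold", {
  cherry <- make_caterpillar(2)
  expect_equal(length(enumerate_histories(cherry, "uDL", 1)), 2)
  expect_equal(length(enumerate_histories(cherry, "uDLT", 1)), 2)
  expect_equal(length(enumerate_histories(make_caterpillar(1), "uDL", 3)), 2)
  # transfers need size >= 2 on each side of the split
  expect_equal(length(enumerate_histories(cherry, "uDLT", 2)), 9)
  for (h in enumerate_histories(cherry, "uDLT", 3))
    expect_equal(nrow(validate_history(h, cherry, "uDLT")), 0)
  expect_error(enumerate_histories(make_caterpillar(5), "uDL", 2), "k <= 4")
})

test_that("a ranking never changes duplication-loss counts (rDL = uDL)", {
  for (k in 2:6) for (tr in enumerate_topologies(k)) {
    u <- history_counts(build_count_tables(tr, "uDL", 20))
    for (s in 1:2) {
      st <- build_time_slices(tr, random_ranking(tr, seed = s))
      expect_identical(history_counts(build_count_tables(st, "rDL", 20)), u)
    }
  }
})

test_that("transfers only enlarge the history space (uDLT >= uDL)", {
  trees <- c(lapply(2:4, make_caterpillar),
             list(make_complete_binary(2), random_topology(6, seed = 2)))
  for (tr in trees) {
    tu <- build_count_tables(tr, "uDL", 10)
    tt <- build_count_tables(tr, "uDLT", 10)
    for (n in 1:10)
      expect_true(history_count(tt, n) >= history_count(tu, n))
  }
})

test_that("counts increase weakly in the history size (n >= 2)", {
  cases <- list(list(make_caterpillar(3), "uDL"),
                list(make_complete_binary(2), "uDLT"))
  tr5 <- make_balanced(5)
  st5 <- build_time_slices(tr5, random_ranking(tr5, 4))
  cases <- c(cases, list(list(st5, "rDLT"), list(st5, "rDTSL")))
  for (cs in cases) {
    tb <- build_count_tables(cs[[1]], cs[[2]], 15)
    for (n in 3:15)
      expect_true(history_count(tb, n) >= history_count(tb, n - 1))
  }
})

test_that("growth estimates match ratio oracles", {
  tb1 <- build_count_tables(make_caterpillar(1), "uDL", 50)
  # Catalan ratio 2(2m-1)/(m+1) at m = 49
  expect_equal(growth_estimate(tb1, 50), 2 * 97 / 50, tolerance = 1e-9)
  expect_equal(round(growth_estimate(tb1, 50), 2), 3.88)
  tb2 <- build_count_tables(make_caterpillar(2), "uDL", 10)
  expect_equal(growth_estimate(tb2, 10), 35066384 / 4310950,
               tolerance = 1e-9)
  expect_equal(growth_estimate(tb2, 2), 7 / 2, tolerance = 1e-12)
  expect_error(growth_estimate(tb2, 1), "n must be")
})

test_that("model/context mismatches are rejected", {
  tr <- make_caterpillar(3)
  st <- build_time_slices(tr, random_ranking(tr, 1))
  expect_error(build_count_tables(tr, "rDLT", 5), "time-sliced")
  expect_error(build_count_tables(st, "uDL", 5), "unranked")
  expect_error(build_count_tables(tr, "nope", 5))
  tb <- build_count_tables(tr, "uDL", 5)
  expect_error(history_count(tb, 6), "n must be")
})
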