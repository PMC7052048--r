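ranked_graph <- function(tree, which_rank = 1) {
  rks <- enumerate_rankings(tree)
  build_events_graph(build_time_slices(tree, rks[[which_rank]]))
}

test_that("events graph invariants: partitions, slice sizes, leaf order", {
  for (s in 1:5) {
    k <- sample(3:7, 1)
    tr <- random_topology(k, seed = 200 + s)
    g <- build_events_graph(build_time_slices(tr, random_ranking(tr, s)))
    for (t in seq_len(k)) {
      members <- g$slices[[t]]
      expect_equal(length(members), t)
      # leaf sets of one slice partition 1..k
      expect_identical(sort(unlist(g$leafset[members])), seq_len(k))
      # complete transfer digraph within the slice: t(t-1) ordered pairs
      expect_equal(length(members) * (length(members) - 1), t * (t - 1))
      # node_at lookup is total and consistent
      for (i in seq_len(k))
        expect_true(i %in% g$leafset[[g$node_at[t, i]]])
    }
    expect_setequal(unlist(g$leafset[g$slices[[k]]]), seq_len(k))
  }
  # a cherry: slice 1 is a singleton (no transfer edges)
  ch <- make_caterpillar(2)
  gch <- ranked_graph(ch)
  expect_equal(length(gch$slices[[1]]), 1)
  dot <- events_graph_dot(gch)
  expect_match(dot, "digraph")
})

test_that("rDT-SL counts are identical across shapes and rankings", {
  for (k in 3:5) {
    vecs <- list()
    for (tr in enumerate_topologies(k))
      for (rk in enumerate_rankings(tr)) {
        tb <- count_dtsl(build_time_slices(tr, rk), 10)
        vecs[[length(vecs) + 1]] <- history_counts(tb)
      }
    expect_gt(length(vecs), if (k >= 4) 2 else 0)
    for (v in vecs) expect_identical(v, vecs[[1]])
  }
  # single-species rDT-SL reduces to duplication trees: Catalan counts
  leaf <- make_caterpillar(1)
  st <- build_time_slices(leaf, enumerate_rankings(leaf)[[1]])
  tb <- count_dtsl(st, 10)
  for (n in 1:10) expect_true(history_count(tb, n) == big_catalan(n - 1))
})

test_that("encode/decode is the identity on sampled histories", {
  tr <- make_complete_binary(2)
  g <- ranked_graph(tr)
  tb <- count_dtsl(g$sliced, 6)
  set.seed(17)
  for (i in 1:100) {
    h <- sample_history(tb, 6)
    enc <- encode_history(h, g)
    expect_identical(serialize_history(decode_history(enc, g)),
                     serialize_history(h))
  }
  # a single surviving lineage encodes as a path through all slices
  single <- decode_history(structure(
    list(slice = 1, leaf = 1, children = list(
      list(slice = 2, leaf = 1, children = list(
        list(slice = 3, leaf = 1, children = list(
          list(slice = 4, leaf = 1, children = list()))))))),
    class = "encoded_history"), g)
  expect_equal(history_size(single), 1)
  expect_equal(nrow(validate_history(single, g$sliced, "rDTSL")), 0)
})

test_that("transport between the two 4-leaf shapes is a bijection", {
  g_bal <- ranked_graph(make_complete_binary(2))
  g_cat <- ranked_graph(make_caterpillar(4))
  tb <- count_dtsl(g_bal$sliced, 6)
  set.seed(31)
  for (i in 1:100) {
    h <- sample_history(tb, 5)
    enc <- encode_history(h, g_bal)
    h2 <- transport_history(enc, g_bal, g_cat)
    expect_equal(nrow(validate_history(h2, g_cat$sliced, "rDTSL")), 0)
    expect_equal(history_size(h2), 5)
    back <- transport_history(encode_history(h2, g_cat), g_cat, g_bal)
    expect_identical(serialize_history(back), serialize_history(h))
  }
  expect_error(transport_history(encode_history(
    sample_history(tb, 2), g_bal), g_bal, ranked_graph(make_caterpillar(3))),
    "same size")
})

test_that("transport is injective on full enumerated sets (k = 4)", {
  g_bal <- ranked_graph(make_complete_binary(2))
  g_cat <- ranked_graph(make_caterpillar(4))
  for (n in 1:3) {
    hs <- enumerate_histories(g_bal$sliced, "rDTSL", n)
    imgs <- vapply(hs, function(h)
      serialize_history(transport_history(encode_history(h, g_bal),
                                          g_bal, g_cat)), "")
    expect_equal(anyDuplicated(imgs), 0)
    # and the image is exactly the target's history set
    target <- vapply(enumerate_histories(g_cat$sliced, "rDTSL", n),
                     serialize_history, "")
    expect_setequal(imgs, target)
  }
})

test_that("iterative tree-growing generates exactly the rDT-SL set", {
  ch <- make_caterpillar(2)
  g <- ranked_graph(ch)
  for (n in 1:4) {
    grown <- sort(vapply(grow_dtsl_histories(g, n), serialize_history, ""))
    enum <- sort(vapply(enumerate_histories(g$sliced, "rDTSL", n),
                        serialize_history, ""))
    expect_identical(grown, enum)
  }
  tr3 <- make_caterpillar(3)
  g3 <- ranked_graph(tr3)
  for (n in 2:3) {
    grown <- sort(vapply(grow_dtsl_histories(g3, n), serialize_history, ""))
    enum <- sort(vapply(enumerate_histories(g3$sliced, "rDTSL", n),
                        serialize_history, ""))
    expect_identical(grown, enum)
  }
})
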