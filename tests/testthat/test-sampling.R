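test_that("sampled histories are valid, sized, and reproducible", {
  cherry <- make_caterpillar(2)
  tb <- build_count_tables(cherry, "uDL", 5)
  h1 <- sample_history(tb, 3, seed = 11)
  h2 <- sample_history(tb, 3, seed = 11)
  expect_identical(serialize_history(h1), serialize_history(h2))
  tr <- make_balanced(5)
  st <- build_time_slices(tr, random_ranking(tr, 2))
  contexts <- list(list(tr, "uDL"), list(tr, "uDLT"),
                   list(st, "rDL"), list(st, "rDLT"), list(st, "rDTSL"))
  for (cs in contexts) {
    tbc <- build_count_tables(cs[[1]], cs[[2]], 8)
    set.seed(5)
    for (i in 1:25) {
      h <- sample_history(tbc, 6)
      expect_equal(history_size(h), 6)
      expect_equal(nrow(validate_history(h, cs[[1]], cs[[2]])), 0)
    }
  }
  expect_error(sample_history(tb, 6), "n must be")
})

test_that("the sampler is uniform over the enumerated support", {
  cases <- list(list(make_caterpillar(2), "uDL", 3, 4000),
                list(make_caterpillar(2), "uDLT", 2, 3000))
  tr3 <- make_caterpillar(3)
  st3 <- build_time_slices(tr3, enumerate_rankings(tr3)[[1]])
  cases <- c(cases, list(list(st3, "rDTSL", 3, 3000)))
  for (cs in cases) {
    ctx <- cs[[1]]; model <- cs[[2]]; n <- cs[[3]]; reps <- cs[[4]]
    support <- vapply(enumerate_histories(ctx, model, n), history_key, "")
    tb <- build_count_tables(ctx, model, n)
    expect_equal(length(support), as.numeric(history_count(tb, n)))
    set.seed(99)
    draws <- vapply(seq_len(reps), function(i)
      history_key(sample_history(tb, n)), "")
    expect_true(all(draws %in% support))
    counts <- table(factor(draws, levels = support))
    expect_gt(chisq_uniform_p(counts), 0.001)
  }
})

test_that("every loss leaf comes from a single-survivor speciation", {
  tr <- make_caterpillar(3)
  tb <- build_count_tables(tr, "uDL", 6)
  set.seed(8)
  for (i in 1:200) {
    h <- sample_history(tb, 6)
    p <- event_profile(h)
    losses_under_s <- 0
    walk <- function(node) {
      if (node$event == "S" && length(node$children) == 2) {
        losses_under_s <<- losses_under_s +
          sum(vapply(node$children, function(c) c$event == "L", TRUE))
      }
      for (c in node$children) walk(c)
    }
    walk(h)
    expect_equal(p$L, losses_under_s)
  }
})

test_that("event profiles tally the tree exactly", {
  cherry <- make_caterpillar(2)
  leafA <- cherry$labels[cherry$children[[cherry$root]][1]]
  leafB <- cherry$labels[cherry$children[[cherry$root]][2]]
  root <- cherry$labels[cherry$root]
  h <- parse_history(sprintf(
    "(%s[&&NHX:event=Extant:species=%s],%s[&&NHX:event=L:species=%s])[&&NHX:event=S:species=%s];",
    leafA, leafA, leafB, leafB, root), cherry)
  p <- event_profile(h)
  expect_equal(p$S, 1); expect_equal(p$L, 1); expect_equal(p$Extant, 1)
  expect_equal(p$score, 1)
  single <- parse_history("A[&&NHX:event=Extant:species=A];",
                          parse_newick("A;"))
  expect_equal(event_profile(single)$score, 0)
  expect_equal(nrow(validate_history(single, parse_newick("A;"), "uDL")), 0)
})

test_that("validation pinpoints broken constraints", {
  cherry <- make_caterpillar(2)
  root <- cherry$labels[cherry$root]
  # duplication whose left child jumps species
  bad <- as_history(list(
    event = "D", species = root,
    children = list(list(event = "Extant", species = "s1", children = list()),
                    list(event = "Extant", species = "s2", children = list()))))
  v <- validate_history(bad, cherry, "uDL")
  expect_true(any(grepl("duplication children species mismatch", v$problem)))
  # transfer at the root: no incomparable receiver exists
  badt <- as_history(list(
    event = "T", species = root,
    children = list(list(event = "Extant", species = "s1", children = list()),
                    list(event = "Extant", species = "s2", children = list()))))
  vt <- validate_history(badt, cherry, "uDLT")
  expect_true(any(grepl("receiver", vt$problem)))
  # transfers are not part of the DL model at all
  expect_true(any(grepl("not allowed", validate_history(badt, cherry,
                                                        "uDL")$problem)))
})

test_that("serialization round-trips sampled histories", {
  tr <- make_balanced(4)
  st <- build_time_slices(tr, random_ranking(tr, 3))
  tb <- build_count_tables(st, "rDLT", 6)
  set.seed(21)
  for (i in 1:100) {
    h <- sample_history(tb, 5)
    txt <- serialize_history(h)
    expect_identical(serialize_history(parse_history(txt, st)), txt)
  }
  expect_identical(
    serialize_history(as_history(list(event = "Extant", species = "s1",
                                      children = list()))),
    "s1[&&NHX:event=Extant:species=s1];")
  expect_error(parse_history("Z[&&NHX:event=Extant:species=Z];", tr),
               "unknown species")
  expect_error(parse_history("s1[&&NHX:event=Bogus:species=s1];", tr),
               "bad event")
})
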