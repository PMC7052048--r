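# Shared fixtures and independent oracles.

# Published counting sequences (exact), n = 1, 2, ...
TABLE3 <- list(
  `1` = c("1", "1", "2", "5", "14", "42", "132", "429", "1430", "4862",
          "16796", "58786", "208012", "742900"),
  `2` = c("2", "7", "34", "200", "1318", "9354", "69864", "541323",
          "4310950", "35066384"),
  `3` = c("3", "19", "159", "1565", "17022", "197928", "2413494",
          "30490089", "395828145"),
  `4` = c("4", "39", "495", "7235", "115303", "1948791", "34379505",
          "626684162"),
  `5` = c("5", "69", "1230", "24843", "541315", "12426996", "296546600",
          "7292489761")
)
TABLE4 <- list(
  `0` = TABLE3[["1"]],
  `1` = TABLE3[["2"]],
  `2` = c("4", "34", "368", "4685", "66416", "1013268", "16279788",
          "271594611", "4660794200"),
  `3` = c("8", "148", "3376", "89390", "2624872", "82866636",
          "2755019736", "95135709027"),
  `4` = c("16", "616", "28832", "1556780", "93017264", "5971377672",
          "403667945712")
)

# Published asymptotics: growth factors (2 d.p.) and constants (4 d.p.)
TABLE2_CAT <- data.frame(
  k = 1:16,
  alpha = c(0.1410, 0.1557, 0.1647, 0.1742, 0.1835, 0.1927, 0.2015,
            0.2101, 0.2184, 0.2265, 0.2342, 0.2418, 0.2491, 0.2563,
            0.2632, 0.2700),
  growth = c(4.00, 9.61, 15.72, 22.69, 30.53, 39.25, 48.84, 59.31,
             70.65, 82.86, 95.93, 109.85, 124.64, 140.28, 156.77, 174.11)
)
TABLE2_CB <- data.frame(
  h = 0:4,
  beta = c(0.1410, 0.1557, 0.1620, 0.1650, 0.1664),
  growth = c(4.00, 9.61, 20.75, 43.02, 87.56)
)

# agreement with a printed value, allowing one ulp in the last digit
expect_printed <- function(value, printed, digits) {
  expect_lt(abs(value - printed), 10^(-digits) / 2 + 10^(-digits) / 10)
}

# number of linear extensions of the internal-node poset, by the hook
# length formula for forests: m! / prod over internal v of (number of
# internal nodes in the subtree of v)
hook_extension_count <- function(tree) {
  internal <- which(lengths(tree$children) == 2L)
  sizes <- integer(0)
  count_internal <- function(i) {
    ch <- tree$children[[i]]
    if (length(ch) == 0L) return(0L)
    s <- 1L + sum(vapply(ch, count_internal, 0L))
    sizes[[length(sizes) + 1L]] <<- s
    s
  }
  count_internal(tree$root)
  factorial(length(internal)) / prod(sizes)
}

# label-free canonical form of a tree's unordered shape
tree_shape_key <- function(tree) {
  rec <- function(i) {
    ch <- tree$children[[i]]
    if (length(ch) == 0L) return("x")
    parts <- sort(vapply(ch, rec, ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  rec(tree$root)
}

ranking_key <- function(rk) {
  internal <- rk$rank < rk$k
  paste(rk$labels[internal][order(rk$rank[internal])], collapse = "|")
}

history_key <- function(h) serialize_history(h)

chisq_uniform_p <- function(observed_counts) {
  stats::chisq.test(observed_counts)$p.value
}
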