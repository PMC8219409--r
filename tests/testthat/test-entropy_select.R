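test_that("class entropy matches hand values", {
  expect_equal(compute_entropy(c(`0` = 5, `1` = 5)), 1.0)
  expect_equal(compute_entropy(c(`0` = 10, `1` = 0)), 0.0)
  # three-class set {a:2, b:3, c:5}, frozen from -sum(p * log2(p))
  expect_equal(compute_entropy(c(a = 2, b = 3, c = 5)), 1.48548,
               tolerance = 1e-5)
  expect_error(compute_entropy(c(0, 0)), "zero")
  expect_error(compute_entropy(c(-1, 2)), "nonnegative")
})

test_that("information gain matches hand-worked partitions", {
  # perfect predictor: gain equals the dataset entropy
  d <- xy_cohort(c(0L, 0L, 1L, 1L, 1L), c(0L, 0L, 1L, 1L, 1L))
  expect_equal(compute_gain(d, "X"), compute_entropy(c(2, 3)))

  # constant feature: no reduction
  d <- xy_cohort(rep(1L, 6), c(0L, 0L, 0L, 0L, 1L, 1L))
  expect_equal(compute_gain(d, "X"), 0)

  # X in {a,a,a,b,b,b}, class {1,1,0,0,0,0}:
  # 0.918296 - (0.5 * 0.918296 + 0.5 * 0) = 0.459148
  d <- xy_cohort(rep(c("a", "b"), each = 3), c(1L, 1L, 0L, 0L, 0L, 0L))
  expect_equal(compute_gain(d, "X"), 0.459148, tolerance = 1e-6)
})

test_that("gain guards: roles, missing values, continuous-looking features", {
  gen <- generate_cohort(generator_config(n_rows = 60, seed = 1))
  expect_error(compute_gain(gen$cohort, "PID"), "role")
  expect_error(compute_gain(gen$cohort, "PTB"), "role")
  expect_error(compute_gain(gen$cohort, "ZZZ"), "unknown")

  withna <- xy_cohort(c(0L, NA, 1L, 0L), c(0L, 1L, 1L, 0L))
  expect_error(compute_gain(withna, "X"), "missing")

  cont <- xy_cohort(seq(0, 1, length.out = 40), rep(c(0L, 1L), 20))
  expect_warning(compute_gain(cont, "X"), "continuous")
})

test_that("range threshold is (max - min) / n", {
  expect_equal(compute_threshold(c(A = 0.9, B = 0.5, C = 0.1)), 0.8 / 3)
  expect_equal(compute_threshold(c(A = 0.3, B = 0.3)), 0)
  expect_equal(compute_threshold(c(A = 0.4, B = 0.2)), 0.1)
  expect_error(compute_threshold(numeric(0)), "no gains")
})

test_that("subset selection keeps gain >= r and reports the cut", {
  # gains are ordered A (1 bit) > B (~0.35) > C (0); r = 1/3 removes C only
  y <- rep(c(1L, 0L), each = 6)
  d <- make_cohort(data.frame(
    A = y,
    B = c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 1L),
    C = rep(c(0L, 1L), 6),
    PTB = y))
  res <- select_subset(d, c("A", "B", "C"))
  g <- res$report$gains
  expect_equal(res$report$threshold, (max(g) - min(g)) / 3)
  expect_equal(res$features, c("A", "B"))
  expect_equal(res$report$n_candidates, 3L)
  # monotone cut: every removed gain below every kept gain
  expect_lt(max(g[setdiff(names(g), res$features)]),
            min(g[res$features]))
})

test_that("all-equal gains give r = 0 and keep everything", {
  y <- rep(c(1L, 0L), 4)
  d <- make_cohort(data.frame(A = y, B = y, PTB = y))
  res <- select_subset(d, c("A", "B"))
  expect_equal(res$report$threshold, 0)
  expect_equal(res$features, c("A", "B"))
})

test_that("a single-class subset keeps all features with a warning", {
  d <- make_cohort(data.frame(A = c(0L, 1L, 0L), B = c(1L, 1L, 0L),
                              PTB = c(0L, 0L, 0L)))
  expect_warning(res <- select_subset(d, c("A", "B")), "single class")
  expect_equal(res$features, c("A", "B"))
  expect_equal(unname(res$report$gains), c(0, 0))
})

test_that("gain matches the first-principles oracle on all small tables", {
  # every 2-class x 3-value contingency table with at most 8 rows
  tables <- enumerate_tables(8L, 3L)
  for (i in seq_len(nrow(tables))) {
    xy <- table_to_xy(tables[i, ], 3L)
    d <- xy_cohort(xy$x, xy$y)
    expect_equal(suppressWarnings(compute_gain(d, "X")),
                 oracle_gain(xy$x, xy$y), tolerance = 1e-12)
  }
})

test_that("gain matches the oracle on random multi-feature tables", {
  withr::with_seed(123, {
    for (rep in 1:200) {
      n <- sample(3:8, 1)
      df <- data.frame(A = sample(0:2, n, TRUE), B = sample(0:1, n, TRUE),
                       C = sample(0:2, n, TRUE), PTB = sample(0:1, n, TRUE))
      d <- make_cohort(df)
      for (f in c("A", "B", "C"))
        expect_equal(suppressWarnings(compute_gain(d, f)),
                     oracle_gain(df[[f]], df$PTB), tolerance = 1e-12)
    }
  })
})

test_that("gain and entropy respect their theoretical bounds", {
  withr::with_seed(2024, {
    for (rep in 1:10000) {
      n <- sample(2:12, 1)
      x <- sample(0:2, n, TRUE)
      y <- sample(0:1, n, TRUE)
      hs <- oracle_entropy(y)
      g <- oracle_gain(x, y)
      expect_gte(g, -1e-12)
      expect_lte(g, hs + 1e-12)
      expect_lte(hs, log2(2) + 1e-12)
    }
  })
})

test_that("three-way partition is stratified, disjoint and exhaustive", {
  gen <- generate_cohort(generator_config(n_rows = 300, prevalence = 0.24,
                                          seed = 9))
  sel <- select_features(gen$cohort, seed = 9)
  a <- sel$subset_assignment
  expect_equal(sort(unique(a)), 1:3)
  expect_equal(length(a), 300L)
  sizes <- table(a)
  expect_lte(max(sizes) - min(sizes), 2L)
  y <- gen$cohort$data$PTB
  for (k in 1:3) {
    mink <- sum(y[a == k])
    expect_lte(abs(mink - sum(y) / 3), 1)
  }
})

test_that("selection invariants: subsets of F0, union, monotone cuts", {
  for (seed in c(3, 14, 15)) {
    gen <- generate_cohort(generator_config(n_rows = 600, seed = seed))
    sel <- select_features(gen$cohort, seed = seed)
    f0 <- sel$initial_features
    expect_true(all(sel$selected_features %in% f0))
    for (k in 1:3) {
      fk <- sel$per_subset_features[[k]]
      expect_true(all(fk %in% f0))
      expect_true(all(fk %in% sel$selected_features))
      g <- sel$gain_reports[[k]]$gains
      removed <- setdiff(names(g), fk)
      if (length(removed) && length(fk))
        expect_lt(max(g[removed]), min(g[fk]))
      expect_true(all(g[fk] >= sel$gain_reports[[k]]$threshold))
    }
  }
})

test_that("selection is deterministic in the seed", {
  gen <- generate_cohort(generator_config(n_rows = 300, seed = 21))
  s1 <- select_features(gen$cohort, seed = 5)
  s2 <- select_features(gen$cohort, seed = 5)
  expect_identical(s1$subset_assignment, s2$subset_assignment)
  expect_identical(s1$selected_features, s2$selected_features)
})

test_that("a lone predictive feature among constants is selected everywhere", {
  y <- rep(c(1L, 0L), each = 15)
  d <- make_cohort(data.frame(GA = y, K1 = rep(1L, 30), K2 = rep(0L, 30),
                              PTB = y))
  sel <- select_features(d, seed = 1)
  for (k in 1:3) expect_equal(sel$per_subset_features[[k]], "GA")
  expect_equal(sel$selected_features, "GA")
})

test_that("identically distributed noise with tied gains keeps F = F0", {
  # constant features tie at gain 0 in every subset, so r = 0 and F = F0
  d <- make_cohort(data.frame(A = rep(1L, 12), B = rep(2L, 12),
                              PTB = rep(c(0L, 1L), 6)))
  sel <- select_features(d, seed = 2)
  expect_equal(sel$selected_features, c("A", "B"))
})

test_that("planted informative features are recovered from the union", {
  hits <- 0L
  for (seed in 1:20) {
    gen <- generate_cohort(generator_config(n_rows = 1300, seed = seed))
    sel <- select_features(gen$cohort, seed = seed)
    if (all(gen$informative %in% sel$selected_features)) hits <- hits + 1L
  }
  # population gains of the planted features are 0.12-0.44 bits, well above
  # the range threshold; allow one stochastic miss in twenty
  expect_gte(hits, 19L)
})

test_that("selection result serializes to JSON and YAML", {
  gen <- generate_cohort(generator_config(n_rows = 120, seed = 3))
  sel <- select_features(gen$cohort, seed = 3)
  pj <- withr::local_tempfile(fileext = ".json")
  py <- withr::local_tempfile(fileext = ".yaml")
  write_selection_result(sel, pj)
  write_selection_result(sel, py)
  back <- jsonlite::read_json(pj)
  expect_equal(unlist(back$selected_features), sel$selected_features)
  expect_equal(unlist(yaml::read_yaml(py)$selected_features),
               sel$selected_features)
})
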