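test_that("minimal hitting sets reproduce the worked sensor families", {
  # three disjoint essential groups of sizes 1, 2, 3 -> 6 minimal sets
  y <- c("x4", "x5", "x6", "x7", "x8", "x9")
  hs <- minimal_hitting_sets(list("x6", c("x4", "x5"), c("x7", "x8", "x9")), y)
  expect_identical(lapply(hs, paste, collapse = ","),
                   list("x4,x6,x7", "x4,x6,x8", "x4,x6,x9",
                        "x5,x6,x7", "x5,x6,x8", "x5,x6,x9"))
  # a singleton group and a pair -> two sets of size two
  hs2 <- minimal_hitting_sets(list("x31", c("x10", "x11")), c("x10", "x11", "x31"))
  expect_true(sets_equal(hs2, list(c("x10", "x31"), c("x11", "x31"))))
  # minimality absorbs supersets
  expect_identical(minimal_hitting_sets(list("a", c("a", "b")), c("a", "b")),
                   list("a"))
  # empty family: the empty set
  expect_identical(minimal_hitting_sets(list(), c("a", "b")), list(character(0)))
})

test_that("hitting-set enumeration matches the subset-lattice oracle on random families", {
  for (seed in 1:8) {
    fam <- mosid:::with_seed(seed, {
      y <- letters[1:sample(6:10, 1)]
      n_sets <- sample(2:5, 1)
      lapply(seq_len(n_sets), function(i) sample(y, sample(1:3, 1)))
    })
    y_max <- letters[1:12]
    expect_true(sets_equal(minimal_hitting_sets(fam, y_max),
                           brute_hitting_sets(fam, y_max)),
                info = sprintf("seed %d", seed))
  }
})

test_that("Bernoulli trial count satisfies the detection bound", {
  # 2 eligible sensors, k = 1 -> q = 0.5, p_hit = 0.25, R = 19
  trials <- bernoulli_subsets(c("a", "b"), 1, mandatory = "m",
                              detection_prob = 0.995, seed = 4,
                              exhaustive_threshold = 0)
  expect_identical(attr(trials, "source"), "bernoulli")
  expect_identical(attr(trials, "trials"), ceiling(log(0.005) / log(0.75)))
  expect_identical(attr(trials, "trials"), 19)
  expect_true(all(vapply(trials, function(s) "m" %in% s, TRUE)))
  # determinism
  t2 <- bernoulli_subsets(c("a", "b"), 1, mandatory = "m",
                          detection_prob = 0.995, seed = 4,
                          exhaustive_threshold = 0)
  expect_identical(unclass(trials), unclass(t2))
})

test_that("small pools defer to exhaustive enumeration", {
  subs <- bernoulli_subsets(letters[1:4], 2, exhaustive_threshold = 10)
  expect_identical(attr(subs, "source"), "exhaustive")
  expect_length(subs, choose(4, 2))
})

test_that("k=1 sweep finds nothing when every single omission keeps identifiability", {
  st <- new_search_state(builtin_model("toy_two_outputs"), seed = 3)
  st <- sweep_omissions(st, 1)
  expect_length(st$records, 0)
})

test_that("two proportional sensors give MOS {{y1}, {y2}} via the full-pair psi", {
  res <- find_minimal_output_sets(builtin_model("toy_two_outputs"), seed = 2)
  expect_length(res$records, 1)
  expect_setequal(res$records[[1]]$psi, c("y1", "y2"))
  expect_true(sets_equal(res$minimal_output_sets, list("y1", "y2")))
  expect_true(res$complete)
})

test_that("search errors when even the full output set fails", {
  expect_error(find_minimal_output_sets(builtin_model("toy_sum"), seed = 2),
               class = "mosid_full_output_unidentifiable")
  expect_error(find_minimal_output_sets(builtin_model("toy_sum"), seed = 2),
               "not possible")
})

test_that("search equals the brute-force subset oracle on small models", {
  for (nm in c("cascade3", "toy_two_outputs")) {
    m <- builtin_model(nm)
    res <- find_minimal_output_sets(m, seed = 6)
    oracle <- brute_mos(m, seed = 6)
    expect_true(sets_equal(res$minimal_output_sets, oracle), info = nm)
  }
  # an identifiable fixture with per-state sensors: MOS must match the oracle
  fx <- make_correlated_fixture("none", n = 3, p = 3, seed = 8)
  res <- find_minimal_output_sets(fx$model, seed = 6)
  expect_true(sets_equal(res$minimal_output_sets, brute_mos(fx$model, seed = 6)))
})

test_that("every returned MOS is identifiable and loses identifiability on any removal", {
  for (nm in c("cascade3", "toy_two_outputs")) {
    m <- builtin_model(nm)
    res <- find_minimal_output_sets(m, seed = 6)
    st <- new_search_state(m, seed = 6)
    for (s in res$minimal_output_sets) {
      expect_identical(mosid:::.subset_test(st, s)$verdict, "identifiable",
                       info = nm)
      for (drop in s) {
        expect_identical(mosid:::.subset_test(st, setdiff(s, drop))$verdict,
                         "unidentifiable",
                         info = sprintf("%s minus %s", nm, drop))
      }
    }
  }
})

test_that("returned MOS satisfy the hitting-set property against the psi family", {
  res <- find_minimal_output_sets(builtin_model("jakstat_nonrational"), seed = 1)
  psis <- lapply(res$records, `[[`, "psi")
  for (s in res$minimal_output_sets)
    for (psi in psis)
      expect_gt(length(intersect(s, psi)), 0)
})

test_that("identical seeds and options give identical results", {
  m <- builtin_model("cascade3")
  r1 <- find_minimal_output_sets(m, seed = 9)
  r2 <- find_minimal_output_sets(m, seed = 9)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(r1$minimal_output_sets, r2$minimal_output_sets)
})

test_that("early-stop check separates sufficient from insufficient candidates", {
  m <- builtin_model("cascade3")
  st <- new_search_state(m, seed = 6)
  chk <- early_stop_check(st, list("x3", c("x1", "x2")))
  expect_identical(chk$verdict[chk$candidate == "x3"], "identifiable")
  expect_identical(chk$verdict[chk$candidate == "x1,x2"], "unidentifiable")
})

test_that("a correlation visible only at k=2 keeps the search going past k=1", {
  # two sensors see the same scaled state: only omitting BOTH hides th1*x1(0)
  m <- builtin_model("toy_two_outputs")
  st <- new_search_state(m, seed = 2)
  st <- sweep_omissions(st, 1)
  expect_length(st$records, 0)           # k=1 finds nothing
  chk <- early_stop_check(st, minimal_hitting_sets(list(), output_labels(m)))
  expect_identical(chk$verdict, "unidentifiable")  # empty candidate: continue
  st <- sweep_omissions(st, 2)
  expect_length(st$records, 1)           # the pair appears at k=2
})
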