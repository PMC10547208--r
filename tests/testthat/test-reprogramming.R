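# Key-gene identification, correlation, usage-set comparison, ratios,
# and the end-to-end analysis bundle.

test_that("key genes are ranked by expression difference", {
  wt <- expression_profile("WT", c(g1 = 2, g2 = 4, g3 = 5))
  ev <- list(expression_profile("Ev1", c(g1 = 2, g2 = 6, g3 = 5)),
             expression_profile("Ev2", c(g1 = 2, g2 = 6, g3 = 5)))
  tab <- identify_key_genes(c("g1", "g2", "g3"), wt, ev, top_k = 1)
  expect_equal(tab$gene[1], "g2")
  expect_equal(tab$delta_expression[1], 2)
  expect_equal(tab$rank, 1:3)
  expect_equal(tab$gene[tab$selected], "g2")
  expect_true(tab$wt_extreme[1])
  # invariant under permutation of the evolved profiles
  tab_rev <- identify_key_genes(c("g1", "g2", "g3"), wt, rev(ev), top_k = 1)
  expect_equal(tab, tab_rev)
  # restricted to the fully-used set
  tab2 <- identify_key_genes(c("g1", "g3"), wt, ev)
  expect_false("g2" %in% tab2$gene)
})

test_that("degenerate and incomplete profiles are handled explicitly", {
  wt <- expression_profile("WT", c(g1 = 2, g2 = 4))
  same <- list(expression_profile("Ev1", c(g1 = 2, g2 = 4)))
  tab <- identify_key_genes(c("g1", "g2"), wt, same)
  expect_false(any(tab$selected))   # zero deltas never selected
  partial <- list(expression_profile("Ev1", c(g1 = 3)))
  expect_warning(tab3 <- identify_key_genes(c("g1", "g2"), wt, partial),
                 "missing from evolved profile")
  expect_equal(tab3$gene, "g1")
})

test_that("pearson correlation matches the closed form and the t test", {
  expect_equal(pearson_correlation(1:3, 1:3)$pearson_r, 1)
  # hand-derived: x=(1,2,3), y=(2,4,7): r = 15/sqrt(228)
  r <- pearson_correlation(c(1, 2, 3), c(2, 4, 7))
  expect_equal(r$pearson_r, 15 / sqrt(228), tolerance = 1e-12)
  expect_equal(round(r$pearson_r, 4), 0.9934)
  # textbook closed form and direct t-CDF on random vectors
  set.seed(11)
  for (k in 1:20) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    rep <- pearson_correlation(x, y)
    rr <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(rep$pearson_r, rr, tolerance = 1e-12)
    tt <- rr * sqrt((n - 2) / (1 - rr^2))
    expect_equal(rep$p_value, 2 * pt(-abs(tt), n - 2), tolerance = 1e-9)
  }
  expect_error(pearson_correlation(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("usage-set regions partition the union", {
  r <- compare_usage_sets(list(A = c("a", "b"), B = c("b", "c")))
  expect_equal(r[["A"]], 1L)
  expect_equal(r[["B"]], 1L)
  expect_equal(r[["A&B"]], 1L)
  same <- compare_usage_sets(list(X = c("a", "b"), Y = c("a", "b"),
                                  Z = c("a", "b")))
  expect_equal(unname(same[["X&Y&Z"]]), 2L)
  expect_length(same, 1L)
  set.seed(5)
  for (k in 1:10) {
    sets <- lapply(1:4, function(i)
      sample(letters, sample(3:10, 1)))
    names(sets) <- paste0("S", 1:4)
    regions <- compare_usage_sets(sets)
    expect_equal(sum(regions), length(unique(unlist(sets))))
  }
  expect_error(compare_usage_sets(rep(list(c("a")), 5)), "4 sets")
  expect_error(compare_usage_sets(list(c("a"))), "at least 2")
})

test_that("score ratios divide and guard against zero", {
  prob <- toy1_problem(C = 1)
  res <- solve_adaptation_score(prob)
  expect_equal(adaptation_score_ratio(res, res), 1)
  res0 <- res; res0$score <- 0L
  expect_error(adaptation_score_ratio(res, res0), "denominator")
  res2 <- res; res2$score <- 1L
  expect_equal(adaptation_score_ratio(res, res2), 2)
})

test_that("the full analysis bundles every stage", {
  profs <- simulate_expression_profiles(toy_spec(), "g2", shift = 2,
                                        n_evolved = 3)
  rep <- run_full_analysis(make_toy_model("toy1"), profs,
                           phenotypes = NULL, medium = toy_medium(), C = 1)
  expect_equal(vapply(rep$unconditional, `[[`, 0L, "score"),
               c(WT = 2L, Ev1 = 2L, Ev2 = 2L, Ev3 = 2L))
  expect_equal(rep$wt_full_usage_set, c("g1", "g2", "g3"))
  expect_equal(rep$key_genes$gene[rep$key_genes$selected], "g2")
  expect_named(rep$conditional, "g2")
  expect_identical(rep$correlations, "not computed")
  expect_length(rep$score_ratios, 4L)
  d <- withr::local_tempdir()
  write_report_bundle(rep, d)
  expect_true(all(c("bundle.json", "keygenes.tsv", "scores.tsv",
                    "conditional_scores.tsv") %in% list.files(d)))
  bundle <- jsonlite::read_json(file.path(d, "bundle.json"))
  expect_equal(bundle$scores$WT, 2L)
  expect_equal(unlist(bundle$key_genes), "g2")

  # with phenotypes the correlation stage runs
  phen <- data.frame(strain = names(profs),
                     growth_rate = c(0.3, 0.52, 0.49, 0.55))
  class(phen) <- c("phenotype_table", "data.frame")
  rep2 <- run_full_analysis(make_toy_model("toy1"), profs,
                            phenotypes = phen, medium = toy_medium(), C = 1)
  expect_true(is.list(rep2$correlations))
})
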