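# Assembly and solution of the adaptation-score MILP on the worked
# instance and on generated fixtures.

test_that("the worked instance assembles with the expected dimensions", {
  prob <- toy1_problem(C = 1)
  expect_equal(prob$P, 3L)
  expect_length(prob$alpha_idx, 3L)
  expect_length(prob$z_idx, 3L)
  expect_equal(2L * prob$n_pairs, 2L)      # one w pair for R3
  expect_equal(prob$n_flux, 6L)
})

test_that("the worked instance scores 2 with the two known optima", {
  prob <- toy1_problem(C = 1)
  res <- solve_adaptation_score(prob)
  expect_equal(res$score, 2L)
  expect_s3_class(res, "adaptation_result")
  # the witness is one of the two optimal usage patterns
  expect_true(paste(sort(res$fully_used_genes), collapse = "+") %in%
                c("g1+g3", "g2+g3"))
  expect_true(check_adaptation_witness(prob, res))
  # g3 is in every optimum; g1 and g2 each in some optimum
  expect_equal(full_usage_gene_set(prob, res), c("g1", "g2", "g3"))
})

test_that("zero conversion constant forces a perfect score", {
  prob <- toy1_problem(C = 0)
  res <- solve_adaptation_score(prob)
  expect_equal(res$score, prob$P)
  expect_equal(sort(res$fully_used_genes), c("g1", "g2", "g3"))
  expect_equal(full_usage_gene_set(prob, res), c("g1", "g2", "g3"))
})

test_that("conditional scoring fixes the target at its maximum", {
  prob <- toy1_problem(C = 1)
  cond_r <- conditional_adaptation_score(prob, "R3")
  expect_equal(cond_r$target_optimum, 5, tolerance = 1e-6)
  expect_equal(cond_r$score, 2L)
  cond_g <- conditional_adaptation_score(prob, "g3")
  expect_equal(cond_g$target_optimum, 5, tolerance = 1e-6)
  expect_equal(cond_g$score, 2L)
  expect_error(conditional_adaptation_score(prob, "nonesuch"),
               "neither a gene nor a reaction")
})

test_that("conditional scores never exceed the unconditional score", {
  for (seed in c(4, 8, 15)) {
    spec <- random_toy_spec(seed)
    conv <- apply_medium(convert_model(make_toy_model(spec)),
                         medium_spec(spec$medium))
    prof <- expression_profile("WT", spec$wt_expr)
    prob <- build_mri_problem(conv, prof, C = 1)
    base <- solve_adaptation_score(prob)
    targets <- c(prob$genes, unique(conv$origin$source))
    for (tg in targets) {
      cond <- suppressWarnings(conditional_adaptation_score(prob, tg))
      expect_lte(cond$score, base$score)
      expect_true(check_adaptation_witness(prob, cond))
    }
  }
})

test_that("the medium closes uptake of unlisted exchanges", {
  spec <- toy2_spec()
  conv <- convert_model(make_toy_model(spec))
  med <- medium_spec("EX_A")
  conv <- apply_medium(conv, med)
  expect_equal(conv$ub[conv$rxn_ids == "EX_D"], 0)   # uptake closed
  expect_equal(conv$ub[conv$rxn_ids == "EX_A"], 1000)
  expect_equal(conv$ub[conv$rxn_ids == "EX_C"], 1000)  # secretion open
  # with D unavailable, g4 can never be fully used at positive expression
  prof <- expression_profile("WT", spec$wt_expr)
  res <- solve_adaptation_score(build_mri_problem(conv, prof, C = 1))
  expect_false("g4" %in% res$fully_used_genes)
  expect_gt(res$alpha_values[["g4"]], 2.9)
  expect_error(apply_medium(conv, medium_spec("EX_AA")), "EX_AA")
})

test_that("the score is invariant to rescaling expression against C", {
  for (seed in c(3, 12)) {
    spec <- random_toy_spec(seed)
    conv <- apply_medium(convert_model(make_toy_model(spec)),
                         medium_spec(spec$medium))
    prof <- expression_profile("WT", spec$wt_expr)
    prof_scaled <- expression_profile("WT", spec$wt_expr * 10)
    s1 <- solve_adaptation_score(build_mri_problem(conv, prof, C = 1))
    s2 <- solve_adaptation_score(build_mri_problem(conv, prof_scaled,
                                                   C = 0.1))
    expect_equal(s1$score, s2$score)
  }
})

test_that("every assembled problem is feasible (all-zero flux floor)", {
  # even a gene with zero expression capacity cannot make the MILP
  # infeasible: alpha_j = E_j C = 0 with z_j free
  spec <- toy_spec("toy1")
  prof <- expression_profile("WT", c(g1 = 0, g2 = 4, g3 = 5))
  expect_warning(
    prob <- build_mri_problem(toy1_converted(), prof, C = 1),
    "below the feasibility tolerance")
  res <- solve_adaptation_score(prob)
  expect_equal(res$solver_status, "optimal")
  # zero-capacity genes are trivially fully used
  expect_true("g1" %in% res$fully_used_genes)
})
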