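# Conversion to the irreversible, without-OR model form and the
# gene -> reaction map.

test_that("irreversible reactions pass through and reversibles split", {
  m <- make_toy_model("toy1")
  conv <- split_reversible(m)
  expect_identical(conv$rxn_ids,
                   c("EX_A", "R1", "R2", "R3_f", "R3_b", "EX_C"))
  expect_true(all(conv$lb >= 0))
  expect_length(conv$opposite_pairs, 1L)
  expect_equal(conv$opposite_pairs[[1]]$source, "R3")
  # backward column is the exact negation of the forward column
  expect_equal(as.numeric(conv$S[, 5]), -as.numeric(conv$S[, 4]))
  expect_equal(conv$ub[4:5], c(1000, 1000))
  # untouched irreversible column
  expect_equal(as.numeric(conv$S[, 2]), as.numeric(m$S[, 2]))
})

test_that("a backward-only reaction is normalized by flipping direction", {
  m <- stoich_model(c("A", "B"), c("EX_A", "R", "EX_B"),
                    matrix(c(1, 0, -1, 1, 0, -1), 2, 3),
                    lb = c(0, -5, 0), ub = c(1000, -1, 1000),
                    gene_rules = c("", "g1", ""))
  conv <- split_reversible(m)
  expect_equal(length(conv$rxn_ids), 3L)   # no split: flipped, not reversible
  k <- which(conv$origin$source == "R")
  expect_equal(conv$origin$direction[k], "bwd")
  expect_equal(c(conv$lb[k], conv$ub[k]), c(1, 5))
  expect_equal(as.numeric(conv$S[, k]), c(1, -1))  # negated column
  expect_length(conv$opposite_pairs, 0L)
})

test_that("isozyme expansion copies columns and splits the gene map", {
  spec <- toy_spec("toy1")
  spec$reactions[[2]]$rule <- "g1 or g1b"           # R1 gains an isozyme
  spec$reactions[[3]]$rule <- "(g2 and g2b) or g2c" # R2 a complex-or-isozyme
  m <- make_toy_model(spec)
  conv <- convert_model(m)
  i1 <- which(conv$origin$source == "R1")
  expect_length(i1, 2L)
  expect_equal(as.numeric(conv$S[, i1[1]]), as.numeric(conv$S[, i1[2]]))
  expect_equal(conv$rule_conjuncts[i1], list("g1", "g1b"))
  i2 <- which(conv$origin$source == "R2")
  expect_equal(conv$rule_conjuncts[i2], list(c("g2", "g2b"), "g2c"))
  # each isozyme gene maps only to its own copy
  expect_equal(conv$gene_map$g1, i1[1])
  expect_equal(conv$gene_map$g1b, i1[2])
  # complex members share their copy
  expect_equal(conv$gene_map$g2, conv$gene_map$g2b)
})

test_that("reversible isozymes oppose all backward copies as one group", {
  spec <- toy_spec("toy1")
  spec$reactions[[4]]$rule <- "g3 or g3b"   # reversible R3 with isozymes
  conv <- convert_model(make_toy_model(spec))
  expect_length(conv$opposite_pairs, 1L)
  pr <- conv$opposite_pairs[[1]]
  expect_length(pr$fwd, 2L)
  expect_length(pr$bwd, 2L)
  for (i in pr$fwd) for (j in pr$bwd)
    expect_equal(as.numeric(conv$S[, j]), -as.numeric(conv$S[, i]))
  # one w pair per source reaction regardless of isozyme count
  prob <- build_mri_problem(apply_medium(conv, toy_medium()),
                            expression_profile("WT", c(g1 = 2, g2 = 4,
                                                       g3 = 3, g3b = 2)),
                            C = 1)
  expect_equal(prob$n_pairs, 1L)
})

test_that("the gene map matches the worked instance and drops aliens", {
  conv <- toy1_converted()
  expect_equal(conv$rxn_ids[conv$gene_map$g3], c("R3_f", "R3_b"))
  prof <- expression_profile("WT", c(g1 = 2, g2 = 4, g3 = 5, alien = 1))
  expect_warning(mapped <- build_gene_map(conv, prof), "alien")
  expect_equal(mapped$P, 3L)
  expect_equal(sort(mapped$mapped_genes), c("g1", "g2", "g3"))
})

test_that("conversion preserves the LP flux space", {
  # restrict uptake so that the optimum is interior to the bounds, then
  # compare max export over the original model (free variables allowed)
  # with the converted model
  for (seed in c(2, 5, 9)) {
    spec <- random_toy_spec(seed)
    m <- make_toy_model(spec)
    up <- which(m$rxn_ids == "EX_in")
    m$ub[up] <- 7
    out <- which(m$rxn_ids == "EX_out")
    obj <- numeric(length(m$rxn_ids)); obj[out] <- 1
    lp0 <- mriscore:::milp_problem(
      obj, m$S, rlb = m$b, rub = m$b, lb = m$lb, ub = m$ub, maximize = TRUE)
    conv <- convert_model(m)
    objc <- numeric(length(conv$rxn_ids))
    objc[which(conv$origin$source == "EX_out" &
                 conv$origin$direction == "fwd")] <- 1
    objc[which(conv$origin$source == "EX_out" &
                 conv$origin$direction == "bwd")] <- -1
    lp1 <- mriscore:::milp_problem(
      objc, conv$S, rlb = conv$b, rub = conv$b, lb = conv$lb, ub = conv$ub,
      maximize = TRUE)
    res <- mriscore:::solve_milp_batch(list(lp0, lp1))
    expect_equal(res[[1]]$objective, res[[2]]$objective, tolerance = 1e-9)
    expect_equal(res[[1]]$objective, 7)  # uptake-limited chain
  }
})

test_that("conversion is idempotent and counts pairs correctly", {
  m <- make_toy_model("toy1")
  c1 <- convert_model(m)
  c2 <- convert_model(c1)
  expect_identical(c1[setdiff(names(c1), "gene_rules")],
                   c2[setdiff(names(c2), "gene_rules")])
  # pair groups = reversible source reactions
  for (seed in 1:6) {
    spec <- random_toy_spec(seed)
    m <- make_toy_model(spec)
    conv <- convert_model(m)
    expect_length(conv$opposite_pairs, sum(m$lb < 0 & m$ub > 0))
  }
})
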