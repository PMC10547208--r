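# Shared fixture builders. TOY1 is the canonical worked instance:
# EX_A -> A, two parallel A->B conversions (g1, g2), reversible B<->C
# (g3), EX_C secretion; wild-type expression g1=2, g2=4, g3=5.

toy1_converted <- function(variant = "toy1") {
  apply_medium(convert_model(make_toy_model(variant)), toy_medium(variant))
}

toy1_wt <- function() {
  simulate_expression_profiles(toy_spec(), "g2", shift = 2,
                               n_evolved = 3)$WT
}

toy1_problem <- function(C = 1) {
  build_mri_problem(toy1_converted(), toy1_wt(), C = C)
}

# a two-uptake variant for medium tests: either A or B can feed the chain
toy2_spec <- function() {
  spec <- toy_spec("toy1")
  spec$name <- "toy2"
  spec$mets <- c(spec$mets, "D")
  spec$reactions <- c(spec$reactions, list(
    list(id = "EX_D", from = character(0), to = "D",
         lb = 0, ub = 1000, rule = ""),
    list(id = "R4", from = "D", to = "B", lb = 0, ub = 1000, rule = "g4")))
  spec$wt_expr <- c(spec$wt_expr, g4 = 3)
  spec
}

pattern_set <- function(patterns) {
  sort(vapply(patterns, function(p) paste(sort(p), collapse = "+"), ""))
}
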