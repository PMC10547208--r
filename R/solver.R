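# Generic linear / mixed-integer linear programming layer. Problems are
# expressed as sparse triplets with two-sided row bounds
# (rlb <= A x <= rub) and solved with HiGHS through scipy.optimize.milp in
# a bundled Python helper. Many problems are batched into a single helper
# invocation to amortize interpreter startup.

MRI_BIG <- 1e30  # sentinel for +/- infinity in the JSON exchange

find_python <- function() {
  py <- getOption("mriscore.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop_mri("no 'python' or 'python3' found on PATH; the MILP backend ",
             "requires Python with scipy")
  unname(py)
}

# Construct an LP/MILP in standard form.
#   obj: length-n objective; A: sparse constraint matrix (may have 0 rows);
#   rlb/rub: row bounds; lb/ub: variable bounds; integer: logical length n.
milp_problem <- function(obj, A, rlb, rub, lb, ub, integer = NULL,
                         maximize = FALSE, time_limit = 600) {
  n <- length(obj)
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                               "generalMatrix"), "TsparseMatrix")
  stopifnot(ncol(A) == n, length(rlb) == nrow(A), length(rub) == nrow(A),
            length(lb) == n, length(ub) == n)
  integer <- if (is.null(integer)) rep(FALSE, n) else as.logical(integer)
  structure(list(obj = as.numeric(obj), A = A,
                 rlb = as.numeric(rlb), rub = as.numeric(rub),
                 lb = as.numeric(lb), ub = as.numeric(ub),
                 integer = integer, maximize = isTRUE(maximize),
                 time_limit = time_limit),
            class = "milp_problem")
}

problem_to_list <- function(p) {
  clamp <- function(x) pmin(pmax(x, -MRI_BIG), MRI_BIG)
  A <- methods::as(methods::as(p$A, "generalMatrix"), "TsparseMatrix")
  list(c = p$obj, maximize = p$maximize,
       nrow = nrow(A), ncol = ncol(A),
       ai = A@i, aj = A@j, ax = A@x,
       rlb = clamp(p$rlb), rub = clamp(p$rub),
       lb = clamp(p$lb), ub = clamp(p$ub),
       integer = as.integer(p$integer),
       time_limit = p$time_limit)
}

#' Solve a batch of LP/MILP problems
#'
#' Internal workhorse around the HiGHS backend. Returns one result per
#' problem: a list with `status` ("optimal", "infeasible", "unbounded",
#' "limit", "error"), `objective`, solution vector `x`, and for
#' mixed-integer problems the dual `bound`.
#'
#' @keywords internal
solve_milp_batch <- function(problems) {
  stopifnot(all(vapply(problems, inherits, TRUE, "milp_problem")))
  if (length(problems) == 0) return(list())
  script <- system.file("python", "milp_batch.py", package = "mriscore",
                        mustWork = TRUE)
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(list(problems = lapply(problems, problem_to_list)),
                       infile, auto_unbox = TRUE, digits = NA)
  status <- system2(find_python(), c(script, infile, outfile),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L) || !file.exists(outfile))
    stop_mri("MILP backend failed (exit status ", status, ")")
  res <- jsonlite::read_json(outfile, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  lapply(res, function(r) {
    r$x <- as.numeric(unlist(r$x))
    r$objective <- as.numeric(r$objective %||% NA_real_)
    r$bound <- as.numeric(r$bound %||% NA_real_)
    r
  })
}

solve_milp <- function(problem) solve_milp_batch(list(problem))[[1]]
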