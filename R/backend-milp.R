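## single shared handle to the python side, created lazily
the <- new.env(parent = emptyenv())

scipy_optimize <- function() {
  if (!is.null(the$scipy_opt)) {
    return(the$scipy_opt)
  }
  if (!reticulate::py_available(initialize = FALSE)) {
    ## auto-discovery may try to fetch an interpreter; point reticulate at the
    ## interpreter on PATH instead
    py <- Sys.which("python")
    if (!nzchar(py)) py <- Sys.which("python3")
    if (nzchar(py)) {
      try(reticulate::use_python(py, required = TRUE), silent = TRUE)
    }
  }
  the$scipy_opt <- reticulate::import("scipy.optimize", delay_load = FALSE)
  the$scipy_opt
}

#' Create an empty mixed-integer feasibility model
#'
#' The model is a pure feasibility problem (constant-zero objective): the
#' minimum decomposition size is found by repeated feasibility probes over k,
#' not by an objective. All variables are integral with explicit finite
#' bounds; constraints are linear with integer coefficients, so any solution
#' returned by [milp_solve()] can be re-validated in exact integer arithmetic.
#'
#' @param backend Name of the solver backend. Only `"highs"` (the HiGHS
#'   solver reached through `scipy.optimize.milp`) ships with the package;
#'   the model container itself is backend-agnostic.
#' @return A `milp_model` object (an environment) to be populated with
#'   [milp_add_vars()] and [milp_add_constraint()].
#' @seealso [milp_solve()]
#' @export
milp_model <- function(backend = "highs") {
  backend <- match.arg(backend, c("highs"))
  m <- new.env(parent = emptyenv())
  m$backend <- backend
  m$nv <- 0L
  m$lb <- numeric(0)
  m$ub <- numeric(0)
  m$nc <- 0L
  m$cons <- vector("list", 64L)
  class(m) <- "milp_model"
  m
}

#' Add a block of integer variables to a model
#'
#' @param model A [milp_model()].
#' @param n Number of variables to add.
#' @param lb,ub Lower/upper bounds, scalars or length-`n` vectors. Bounds
#'   must be finite: every variable carries explicit finite bounds.
#' @return Integer vector of the new variable indices.
#' @export
milp_add_vars <- function(model, n, lb = 0, ub = 1) {
  stopifnot(inherits(model, "milp_model"), n >= 0)
  if (n == 0) return(integer(0))
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    rlang::abort("all variable bounds must be finite")
  }
  if (any(ub < lb)) rlang::abort("upper bound below lower bound")
  idx <- model$nv + seq_len(n)
  model$lb <- c(model$lb, lb)
  model$ub <- c(model$ub, ub)
  model$nv <- model$nv + as.integer(n)
  idx
}

#' Add a linear constraint lo <= coef . x[idx] <= hi
#'
#' @param model A [milp_model()].
#' @param idx Variable indices.
#' @param coef Coefficients (same length as `idx`).
#' @param lo,hi Constraint bounds; use `-Inf`/`Inf` for one-sided rows.
#' @return The model, invisibly.
#' @export
milp_add_constraint <- function(model, idx, coef, lo = -Inf, hi = Inf) {
  stopifnot(length(idx) == length(coef))
  if (length(idx) == 0) return(invisible(model))
  if (any(idx < 1 | idx > model$nv)) rlang::abort("constraint references unknown variable")
  i <- model$nc + 1L
  if (i > length(model$cons)) {
    length(model$cons) <- 2L * length(model$cons)
  }
  model$cons[[i]] <- list(idx = as.integer(idx), coef = as.numeric(coef),
                          lo = as.numeric(lo), hi = as.numeric(hi))
  model$nc <- i
  invisible(model)
}

#' Solve a feasibility model
#'
#' Hands the model to the HiGHS solver and post-processes the raw solution:
#' values are rounded to the nearest integer (tolerance `1e-5`; a larger
#' deviation is an error, signalling solver tolerance failure) and every
#' constraint is then re-checked in exact integer arithmetic, so the
#' reported feasibility never depends on floating-point slack.
#'
#' @param model A populated [milp_model()].
#' @param time_limit Wall-clock limit in seconds (`Inf` for none).
#' @return A list with `status` (`"feasible"`, `"infeasible"` or
#'   `"timeout"`) and, when feasible, `values`: the integral assignment.
#' @export
milp_solve <- function(model, time_limit = Inf) {
  stopifnot(inherits(model, "milp_model"))
  nv <- model$nv
  if (nv == 0L) {
    return(list(status = "feasible", values = numeric(0)))
  }
  sp <- scipy_optimize()
  nc <- model$nc
  constraints <- NULL
  if (nc > 0L) {
    A <- matrix(0, nrow = nc, ncol = nv)
    lo <- numeric(nc)
    hi <- numeric(nc)
    for (i in seq_len(nc)) {
      cn <- model$cons[[i]]
      A[cbind(rep.int(i, length(cn$idx)), cn$idx)] <- cn$coef
      lo[i] <- cn$lo
      hi[i] <- cn$hi
    }
    constraints <- sp$LinearConstraint(A, lo, hi)
  }
  opts <- list(presolve = TRUE)
  if (is.finite(time_limit)) opts$time_limit <- as.numeric(time_limit)
  res <- sp$milp(
    c = numeric(nv),
    integrality = rep(1L, nv),
    bounds = sp$Bounds(model$lb, model$ub),
    constraints = constraints,
    options = opts
  )
  status <- as.integer(res$status)
  if (status == 2L) {
    return(list(status = "infeasible", values = NULL))
  }
  if (status == 1L) {
    return(list(status = "timeout", values = NULL))
  }
  if (status != 0L) {
    rlang::abort(paste0("solver backend failure: ", as.character(res$message)))
  }
  x <- as.numeric(res$x)
  r <- round(x)
  if (max(abs(x - r)) > 1e-5) {
    rlang::abort("solver returned a non-integral assignment beyond tolerance 1e-5")
  }
  check_integral_assignment(model, r)
  list(status = "feasible", values = r)
}

## exact re-validation of bounds and every constraint on the rounded solution
check_integral_assignment <- function(model, r) {
  if (any(r < model$lb - 0.5) || any(r > model$ub + 0.5)) {
    rlang::abort("rounded assignment violates variable bounds")
  }
  for (i in seq_len(model$nc)) {
    cn <- model$cons[[i]]
    val <- sum(cn$coef * r[cn$idx])
    if (val < cn$lo - 1e-9 || val > cn$hi + 1e-9) {
      rlang::abort("rounded assignment violates a constraint under exact re-check")
    }
  }
  invisible(TRUE)
}

#' @export
print.milp_model <- function(x, ...) {
  cat("<milp_model> ", x$nv, " variables, ", x$nc, " constraints, backend ",
      x$backend, "\n", sep = "")
  invisible(x)
}
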