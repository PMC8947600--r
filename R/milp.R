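# Branch-and-bound mixed-integer solver on top of the dense simplex.
#
# The cut-set search poses MILPs with a handful of binary row-selection
# variables, so plain depth-first branch and bound with LP-relaxation
# bounding closes them quickly.

#' Solve a small mixed-integer linear program
#'
#' Depth-first branch and bound; integrality is enforced on `int_idx` by
#' adding unit-row bound constraints at each branching step. Upper bounds
#' on the integer variables (e.g. `z <= 1` for binaries) must be part of
#' the constraint system supplied by the caller.
#'
#' @param obj,A,dir,rhs as in [lp_solve()].
#' @param int_idx indices of integer-constrained variables.
#' @param maximize maximise instead of minimise?
#' @param time_limit wall-clock seconds before the search stops and the
#'   incumbent (if any) is returned.
#' @param integral_objective when `TRUE` the objective is known to take
#'   integer values at feasible points, which sharpens the bound.
#' @param int_tol integrality tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`,
#'   `"timeout_incumbent"`, `"timeout"`), `objective`, `x`.
#' @keywords internal
milp_solve <- function(obj, A, dir, rhs, int_idx,
                       maximize = FALSE, time_limit = Inf,
                       integral_objective = FALSE, int_tol = 1e-6) {
  A <- as.matrix(A)
  n <- ncol(A)
  sgn <- if (maximize) -1 else 1
  cost <- sgn * obj # minimise throughout

  t0 <- proc.time()[["elapsed"]]
  incumbent <- NULL
  inc_obj <- Inf
  timed_out <- FALSE

  unit_row <- function(i) {
    r <- numeric(n)
    r[i] <- 1
    r
  }

  # each node is a list of extra (row, dir, rhs) branching constraints
  stack <- list(list())
  while (length(stack) > 0L) {
    if (proc.time()[["elapsed"]] - t0 > time_limit) {
      timed_out <- TRUE
      break
    }
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL

    if (length(node) > 0L) {
      extraA <- do.call(rbind, lapply(node, `[[`, "row"))
      nA <- rbind(A, extraA)
      ndir <- c(dir, vapply(node, `[[`, character(1), "dir"))
      nrhs <- c(rhs, vapply(node, `[[`, numeric(1), "rhs"))
    } else {
      nA <- A
      ndir <- dir
      nrhs <- rhs
    }
    rel <- lp_solve(cost, nA, ndir, nrhs, maximize = FALSE)
    if (rel$status != "optimal") next
    bound <- rel$objective
    if (integral_objective) bound <- ceiling(bound - 1e-6)
    if (bound >= inc_obj - 1e-9) next

    frac <- abs(rel$x[int_idx] - round(rel$x[int_idx]))
    if (all(frac <= int_tol)) {
      x <- rel$x
      x[int_idx] <- round(x[int_idx])
      incumbent <- x
      inc_obj <- rel$objective
      next
    }
    bvar <- int_idx[which.max(frac)]
    bval <- rel$x[bvar]
    dn <- c(node, list(list(row = unit_row(bvar), dir = "<=", rhs = floor(bval))))
    up <- c(node, list(list(row = unit_row(bvar), dir = ">=", rhs = ceiling(bval))))
    # explore the "up" branch first: for minimal cut sets, fixing a row in
    # tends to reach integer-feasible selections sooner
    stack[[length(stack) + 1L]] <- dn
    stack[[length(stack) + 1L]] <- up
  }

  if (is.null(incumbent)) {
    status <- if (timed_out) "timeout" else "infeasible"
    return(list(status = status, objective = NA_real_, x = rep(NA_real_, n)))
  }
  status <- if (timed_out) "timeout_incumbent" else "optimal"
  list(status = status, objective = sgn * inc_obj, x = incumbent)
}
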