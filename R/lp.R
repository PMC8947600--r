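# Dense two-phase primal simplex.
#
# All linear programs in this package (flux maximisation, cut-set
# verification, the relaxations inside the branch-and-bound search) are
# small -- tens of variables and constraints -- so a dense tableau with
# Bland's anti-cycling rule is both adequate and dependable.

#' Solve a small dense linear program
#'
#' Minimises (or maximises) `obj %*% x` subject to `A x (dir) rhs` and
#' `x >= 0`, by the two-phase primal simplex method with Bland's rule.
#'
#' @param obj numeric objective coefficients, length `n`.
#' @param A constraint matrix, `m x n`.
#' @param dir character vector of `"<="`, `">="`, `"=="`, length `m`.
#' @param rhs numeric right-hand sides, length `m`.
#' @param maximize maximise instead of minimise?
#' @param tol numeric pivot tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective`, and the primal solution `x`.
#' @keywords internal
lp_solve <- function(obj, A, dir, rhs, maximize = FALSE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(dir) == m, length(rhs) == m)
  if (m == 0L) {
    # only x >= 0: optimum at origin unless improving direction is unbounded
    improving <- if (maximize) any(obj > tol) else any(obj < -tol)
    if (improving) {
      return(list(status = "unbounded", objective = NA_real_, x = rep(NA_real_, n)))
    }
    return(list(status = "optimal", objective = 0, x = numeric(n)))
  }

  # normalise to rhs >= 0
  flip <- rhs < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    rhs[flip] <- -rhs[flip]
    dir[flip] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[dir[flip]]
  }

  cost <- if (maximize) -obj else obj

  # augment with slack / surplus / artificial columns
  n_slack <- sum(dir != "==")
  slack_sign <- ifelse(dir == "<=", 1, -1)
  need_art <- dir != "<="
  n_art <- sum(need_art)
  nc <- n + n_slack + n_art

  Tb <- matrix(0, m, nc + 1L)
  Tb[, seq_len(n)] <- A
  Tb[, nc + 1L] <- rhs
  slack_col <- integer(m)
  art_col <- integer(m)
  sc <- n
  for (i in seq_len(m)) {
    if (dir[i] != "==") {
      sc <- sc + 1L
      Tb[i, sc] <- slack_sign[i]
      slack_col[i] <- sc
    }
  }
  ac <- n + n_slack
  for (i in seq_len(m)) {
    if (need_art[i]) {
      ac <- ac + 1L
      Tb[i, ac] <- 1
      art_col[i] <- ac
    }
  }
  basis <- ifelse(need_art, art_col, slack_col)

  art_cols <- seq.int(n + n_slack + 1L, length.out = n_art)
  phase1_cost <- numeric(nc)
  phase1_cost[art_cols] <- 1
  phase2_cost <- c(cost, numeric(nc - n))
  max_iter <- 2000L + 200L * (m + nc)

  run_phase <- function(Tb, basis, cvec, forbid = integer(0)) {
    for (iter in seq_len(max_iter)) {
      cb <- cvec[basis]
      red <- cvec - as.vector(cb %*% Tb[, seq_len(nc), drop = FALSE])
      cand <- which(red < -tol)
      cand <- setdiff(cand, forbid)
      if (length(cand) == 0L) {
        return(list(Tb = Tb, basis = basis, status = "optimal"))
      }
      j <- min(cand) # Bland's rule
      col <- Tb[, j]
      pos <- which(col > tol)
      if (length(pos) == 0L) {
        return(list(Tb = Tb, basis = basis, status = "unbounded"))
      }
      theta <- Tb[pos, nc + 1L] / col[pos]
      tmin <- min(theta)
      ties <- pos[theta <= tmin + tol]
      r <- ties[which.min(basis[ties])] # Bland tie-break on leaving index
      piv <- Tb[r, j]
      Tb[r, ] <- Tb[r, ] / piv
      other <- setdiff(seq_len(m), r)
      if (length(other) > 0L) {
        Tb[other, ] <- Tb[other, , drop = FALSE] - outer(Tb[other, j], Tb[r, ])
      }
      basis[r] <- j
    }
    stop("simplex iteration limit exceeded", call. = FALSE)
  }

  if (n_art > 0L) {
    ph1 <- run_phase(Tb, basis, phase1_cost)
    Tb <- ph1$Tb
    basis <- ph1$basis
    p1obj <- sum(phase1_cost[basis] * Tb[, nc + 1L])
    if (p1obj > 1e-7 * max(1, max(abs(rhs)))) {
      return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
    }
    # drive residual artificials out of the basis (value ~ 0)
    drop_rows <- integer(0)
    for (i in seq_len(m)) {
      if (basis[i] %in% art_cols) {
        cand <- setdiff(which(abs(Tb[i, seq_len(n + n_slack)]) > tol), art_cols)
        if (length(cand) == 0L) {
          drop_rows <- c(drop_rows, i) # redundant constraint
        } else {
          j <- cand[1L]
          piv <- Tb[i, j]
          Tb[i, ] <- Tb[i, ] / piv
          other <- setdiff(seq_len(m), i)
          if (length(other) > 0L) {
            Tb[other, ] <- Tb[other, , drop = FALSE] - outer(Tb[other, j], Tb[i, ])
          }
          basis[i] <- j
        }
      }
    }
    if (length(drop_rows) > 0L) {
      Tb <- Tb[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
      m <- nrow(Tb)
    }
  }

  ph2 <- run_phase(Tb, basis, phase2_cost, forbid = art_cols)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_, x = rep(NA_real_, n)))
  }
  Tb <- ph2$Tb
  basis <- ph2$basis
  x_full <- numeric(nc)
  x_full[basis] <- Tb[, nc + 1L]
  x <- x_full[seq_len(n)]
  objective <- sum(obj * x)
  list(status = "optimal", objective = objective, x = x)
}
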