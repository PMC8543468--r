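#' Solve a bounded linear program
#'
#' Dense two-phase tableau simplex presenting the general form
#' \deqn{\min c'x \quad s.t.\quad A_{eq} x = b_{eq},\; A_{ub} x \le b_{ub},\;
#' lb \le x \le ub.}
#' Variables are shifted by their (finite) lower bounds, finite upper
#' bounds become inequality rows, and fixed variables (`lb == ub`) are
#' substituted out before solving. Pivoting uses the steepest reduced
#' cost (Dantzig) rule and falls back to Bland's rule after an iteration
#' budget, so degenerate problems cannot cycle. Problem sizes here are
#' tiny (tens of variables), where a dense tableau is the right tool.
#'
#' @param obj numeric objective coefficients, length n.
#' @param A_eq,b_eq equality constraints (matrix m_eq x n, or NULL).
#' @param A_ub,b_ub inequality constraints `A_ub x <= b_ub` (or NULL).
#' @param lb,ub variable bounds; must be finite (callers substitute the
#'   model's sentinel bound for infinities beforehand).
#' @param maximize maximize instead of minimize.
#' @param n_iter unused compatibility argument (iteration budget is
#'   derived from the problem size).
#'
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `x` (solution on the original scale) and `objective`.
#' @keywords internal
solve_lp <- function(obj, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                     lb, ub, maximize = FALSE, n_iter = NULL) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite bounds; substitute sentinel bounds first")
  fail <- function(status) list(status = status, x = rep(NA_real_, n),
                                objective = NA_real_)
  if (any(lb > ub + 1e-12)) return(fail("infeasible"))

  # substitute out fixed variables: exact, and shrinks the tableau
  rng_all <- ub - lb
  fixed <- rng_all <= 1e-12
  if (any(fixed)) {
    xfix <- lb
    free <- which(!fixed)
    shift_eq <- if (!is.null(A_eq)) as.numeric(A_eq[, fixed, drop = FALSE] %*% lb[fixed]) else NULL
    shift_ub <- if (!is.null(A_ub)) as.numeric(A_ub[, fixed, drop = FALSE] %*% lb[fixed]) else NULL
    if (!length(free)) {
      ok <- TRUE
      if (!is.null(A_eq)) ok <- ok && all(abs(shift_eq - b_eq) <= 1e-9)
      if (!is.null(A_ub)) ok <- ok && all(shift_ub <= b_ub + 1e-9)
      return(if (ok) list(status = "optimal", x = xfix, objective = sum(obj * xfix))
             else fail("infeasible"))
    }
    sub <- solve_lp(obj[free],
                    A_eq = if (!is.null(A_eq)) A_eq[, free, drop = FALSE] else NULL,
                    b_eq = if (!is.null(b_eq)) b_eq - shift_eq else NULL,
                    A_ub = if (!is.null(A_ub)) A_ub[, free, drop = FALSE] else NULL,
                    b_ub = if (!is.null(b_ub)) b_ub - shift_ub else NULL,
                    lb = lb[free], ub = ub[free], maximize = maximize)
    if (sub$status != "optimal") return(fail(sub$status))
    x <- xfix
    x[free] <- sub$x
    return(list(status = "optimal", x = x, objective = sum(obj * x)))
  }

  # shift x = y + lb, y in [0, rng]
  cvec <- if (maximize) -obj else obj
  G <- diag(1, n); h <- rng_all; tp <- rep("<=", n)
  if (!is.null(A_ub) && NROW(A_ub) > 0) {
    G <- rbind(G, A_ub)
    h <- c(h, b_ub - as.numeric(A_ub %*% lb))
    tp <- c(tp, rep("<=", NROW(A_ub)))
  }
  if (!is.null(A_eq) && NROW(A_eq) > 0) {
    G <- rbind(G, A_eq)
    h <- c(h, b_eq - as.numeric(A_eq %*% lb))
    tp <- c(tp, rep("==", NROW(A_eq)))
  }

  res <- simplex_core(cvec, G, h, tp)
  if (res$status != "optimal") return(fail(res$status))
  x <- res$x + lb
  names(x) <- names(obj)
  list(status = "optimal", x = x, objective = sum(obj * x))
}

# two-phase primal simplex on: min c'y, G y (<=|>=|==) h, y >= 0.
# Dense tableau; Dantzig pricing with a Bland fallback for anti-cycling.
simplex_core <- function(cvec, G, h, tp, eps = 1e-9) {
  n0 <- length(cvec)
  m <- length(h)

  # normalize rows to nonnegative rhs
  flip <- h < 0
  if (any(flip)) {
    G[flip, ] <- -G[flip, , drop = FALSE]
    h[flip] <- -h[flip]
    tp[flip] <- ifelse(tp[flip] == "<=", ">=", ifelse(tp[flip] == ">=", "<=", "=="))
  }

  # slack (+1) for <=, surplus (-1) + artificial for >=, artificial for ==
  n_slack <- sum(tp == "<=") + sum(tp == ">=")
  n_art <- sum(tp != "<=")
  A <- cbind(G, matrix(0, m, n_slack + n_art))
  basis <- integer(m)
  js <- n0; ja <- n0 + n_slack
  for (i in seq_len(m)) {
    if (tp[i] == "<=") {
      js <- js + 1L; A[i, js] <- 1; basis[i] <- js
    } else if (tp[i] == ">=") {
      js <- js + 1L; A[i, js] <- -1
      ja <- ja + 1L; A[i, ja] <- 1; basis[i] <- ja
    } else {
      ja <- ja + 1L; A[i, ja] <- 1; basis[i] <- ja
    }
  }
  ntot <- ncol(A)
  art_cols <- seq.int(n0 + n_slack + 1L, length.out = n_art)
  b <- h

  run_phase <- function(A, b, basis, cost, banned) {
    m <- nrow(A); ntot <- ncol(A)
    max_it <- 50L * (m + ntot) + 1000L
    bland_after <- 10L * (m + ntot) + 200L
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_it) return(list(status = "maxiter"))
      cb <- cost[basis]
      # reduced costs d = c - c_B^T A (rows of A are already B^{-1} A)
      d <- cost - as.numeric(crossprod(A, cb))
      d[banned] <- Inf
      d[basis] <- Inf  # basic columns are never entering
      cand <- which(d < -eps)
      if (!length(cand)) {
        x <- numeric(ntot); x[basis] <- b
        return(list(status = "optimal", A = A, b = b, basis = basis, x = x))
      }
      j <- if (it > bland_after) cand[1L] else cand[which.min(d[cand])]
      col <- A[, j]
      pos <- which(col > eps)
      if (!length(pos)) return(list(status = "unbounded"))
      ratio <- b[pos] / col[pos]
      rmin <- min(ratio)
      ties <- pos[ratio <= rmin + eps * (1 + abs(rmin))]
      i <- ties[which.min(basis[ties])]  # Bland-style tie break on leaving var
      # pivot on (i, j)
      piv <- A[i, j]
      A[i, ] <- A[i, ] / piv
      b[i] <- b[i] / piv
      other <- setdiff(seq_len(m), i)
      fac <- A[other, j]
      A[other, ] <- A[other, ] - outer(fac, A[i, ])
      b[other] <- b[other] - fac * b[i]
      b[b < 0 & b > -1e-11] <- 0
      basis[i] <- j
    }
  }

  if (n_art > 0) {
    cost1 <- numeric(ntot); cost1[art_cols] <- 1
    p1 <- run_phase(A, b, basis, cost1, banned = integer(0))
    if (p1$status != "optimal") return(list(status = "infeasible"))
    if (sum(abs(p1$x[art_cols])) > 1e-7)
      return(list(status = "infeasible"))
    A <- p1$A; b <- p1$b; basis <- p1$basis
    # drive leftover zero-level artificials out of the basis
    for (i in which(basis %in% art_cols)) {
      j <- which(abs(A[i, seq_len(n0 + n_slack)]) > eps)[1L]
      if (is.na(j)) { b[i] <- 0; next }  # redundant row; keep inert
      piv <- A[i, j]
      A[i, ] <- A[i, ] / piv; b[i] <- b[i] / piv
      other <- setdiff(seq_len(m), i)
      fac <- A[other, j]
      A[other, ] <- A[other, ] - outer(fac, A[i, ])
      b[other] <- b[other] - fac * b[i]
      basis[i] <- j
    }
  }

  cost2 <- c(cvec, numeric(ntot - n0))
  p2 <- run_phase(A, b, basis, cost2, banned = art_cols)
  if (p2$status == "maxiter") return(list(status = "infeasible"))
  if (p2$status != "optimal") return(p2)
  list(status = "optimal", x = p2$x[seq_len(n0)],
       objective = sum(cvec * p2$x[seq_len(n0)]))
}
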