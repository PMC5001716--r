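#' Solve a bounded-variable linear program
#'
#' Maximises \code{obj \%*\% x} subject to \code{A x = b} and
#' \code{lb <= x <= ub}, using a two-phase primal simplex with explicit
#' variable bounds. Steady-state flux problems are maximally degenerate
#' (\code{b = 0}), so the pivoting rule switches to Bland's rule after an
#' iteration threshold to guarantee termination.
#'
#' @param obj numeric objective vector (length n).
#' @param A dense or sparse constraint matrix (m x n).
#' @param b right-hand side (length m).
#' @param lb,ub finite lower/upper bounds (length n).
#' @param maximize logical; minimises when \code{FALSE}.
#' @param tol pivot/feasibility tolerance.
#' @return list with \code{status} ("optimal", "infeasible" or "maxit"),
#'   \code{x} (primal solution) and \code{objval}.
#' @export
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) return(list(status = "infeasible", x = NULL, objval = NA_real_))
  if (!maximize) {
    res <- lp_solve(-obj, A, b, lb, ub, maximize = TRUE, tol = tol)
    if (!is.null(res$objval)) res$objval <- -res$objval
    return(res)
  }
  if (m == 0L) {
    x <- ifelse(obj > 0, ub, lb)
    return(list(status = "optimal", x = x, objval = sum(obj * x)))
  }

  # Phase 1: structural variables nonbasic at lb, artificials close the residual
  x0 <- lb
  r <- b - as.numeric(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)
  Aall <- cbind(A, diag(sgn, m))
  lball <- c(lb, rep(0, m))
  uball <- c(ub, rep(Inf, m))
  nall <- n + m
  state <- list(
    basis = (n + 1L):nall,
    at_upper = rep(FALSE, nall),          # bound status of nonbasic variables
    Binv = diag(1 / sgn, m),
    xB = abs(r)
  )
  c1 <- c(rep(0, n), rep(-1, m))
  state <- simplex_core(c1, Aall, b, lball, uball, state, tol)
  if (state$status == "maxit") return(list(status = "maxit", x = NULL, objval = NA_real_))
  phase1 <- sum(c1[state$basis] * state$xB)
  if (phase1 < -1e-7) return(list(status = "infeasible", x = NULL, objval = NA_real_))

  # Phase 2: pin artificials to zero, optimise the real objective
  uball[(n + 1L):nall] <- 0
  state$xB[state$basis > n] <- 0
  c2 <- c(obj, rep(0, m))
  state <- simplex_core(c2, Aall, b, lball, uball, state, tol)
  if (state$status == "maxit") return(list(status = "maxit", x = NULL, objval = NA_real_))
  x <- numeric(nall)
  x[] <- ifelse(state$at_upper, uball, lball)
  x[!is.finite(x)] <- 0
  x[state$basis] <- state$xB
  x <- x[seq_len(n)]
  list(status = "optimal", x = x, objval = sum(obj * x))
}

# Bounded-variable simplex iterations on max c'x, Ax = b, lb <= x <= ub,
# starting from the basic solution described by `state`.
simplex_core <- function(cc, A, b, lb, ub, state, tol) {
  m <- nrow(A); n <- ncol(A)
  basis <- state$basis; at_upper <- state$at_upper
  Binv <- state$Binv; xB <- state$xB
  maxit <- 200L * (n + m) + 1000L
  bland_after <- 20L * (n + m) + 200L
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > maxit) {
      return(list(status = "maxit", basis = basis, at_upper = at_upper,
                  Binv = Binv, xB = xB))
    }
    if (it %% 200L == 0L) {               # refactorize to limit drift
      Binv <- solve(A[, basis, drop = FALSE])
      nb <- setdiff(seq_len(n), basis)
      xN <- ifelse(at_upper[nb], ub[nb], lb[nb])
      xN[!is.finite(xN)] <- 0
      xB <- as.numeric(Binv %*% (b - A[, nb, drop = FALSE] %*% xN))
    }
    y <- as.numeric(crossprod(cc[basis], Binv))
    d <- cc - as.numeric(y %*% A)
    d[basis] <- 0
    is_basic <- logical(n); is_basic[basis] <- TRUE
    up_ok <- !is_basic & !at_upper & d > tol & (ub - lb) > tol
    dn_ok <- !is_basic & at_upper & d < -tol & (ub - lb) > tol
    elig <- which(up_ok | dn_ok)
    if (!length(elig)) {
      return(list(status = "optimal", basis = basis, at_upper = at_upper,
                  Binv = Binv, xB = xB))
    }
    bland <- it > bland_after
    j <- if (bland) elig[1L] else elig[which.max(abs(d[elig]))]
    s <- if (at_upper[j]) -1 else 1       # direction of change of x_j
    start_j <- if (at_upper[j]) ub[j] else lb[j]
    w <- as.numeric(Binv %*% A[, j])
    # ratio test: how far x_j may move before it or a basic variable hits a bound
    cand_t <- ub[j] - lb[j]               # own bound flip
    cand_leave <- 0L; cand_to_upper <- FALSE
    dw <- s * w
    dec <- which(dw > tol)                # basic vars pushed toward their lb
    inc <- which(dw < -tol)               # basic vars pushed toward their ub
    ratios <- c(
      if (length(dec)) (xB[dec] - lb[basis[dec]]) / dw[dec] else numeric(),
      if (length(inc)) (ub[basis[inc]] - xB[inc]) / (-dw[inc]) else numeric()
    )
    rows <- c(dec, inc)
    to_up <- c(rep(FALSE, length(dec)), rep(TRUE, length(inc)))
    keep <- is.finite(ratios)
    ratios <- pmax(ratios[keep], 0); rows <- rows[keep]; to_up <- to_up[keep]
    if (length(ratios)) {
      rmin <- min(ratios)
      if (rmin <= cand_t + 1e-12) {
        k <- which(ratios <= rmin + 1e-12)
        k <- if (bland) k[which.min(basis[rows[k]])] else k[which.max(abs(dw[rows[k]]))]
        cand_t <- rmin; cand_leave <- rows[k]; cand_to_upper <- to_up[k]
      }
    }
    if (!is.finite(cand_t)) {
      # unbounded direction; only possible through infinite-ub artificials
      return(list(status = "maxit", basis = basis, at_upper = at_upper,
                  Binv = Binv, xB = xB))
    }
    xB <- xB - s * cand_t * w
    if (cand_leave == 0L) {               # bound flip, basis unchanged
      at_upper[j] <- !at_upper[j]
      next
    }
    lv <- basis[cand_leave]
    at_upper[lv] <- cand_to_upper
    basis[cand_leave] <- j
    at_upper[j] <- FALSE
    xB[cand_leave] <- start_j + s * cand_t
    leave <- cand_leave
    piv <- w[leave]
    Brow <- Binv[leave, ] / piv
    Binv <- Binv - w %o% Brow
    Binv[leave, ] <- Brow
    next
  }
}
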