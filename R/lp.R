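#' Dense two-phase simplex linear-programming kernel
#'
#' Solves  optimise c'v  subject to  S v = 0,  lb <= v <= ub  (all bounds
#' finite). Variables are shifted to x = v - lb >= 0 and upper bounds are
#' handled through explicit slack rows, giving the standard form tackled by
#' a textbook two-phase tableau simplex. Bland's smallest-index rule is
#' used throughout, which guarantees termination (no cycling) at the cost
#' of speed -- an acceptable trade for the small and medium problems this
#' package solves, where robustness of degenerate bases matters more than
#' iteration count. Deterministic and single-threaded by construction.
#'
#' @noRd
NULL

LP_TOL <- 1e-9

# minimise d' z over the current tableau; returns updated state
# T: (m_rows) x (N+1) tableau (last column = RHS), basis: row -> column.
# Pricing: Dantzig (most negative reduced cost) while the objective keeps
# moving; on a degenerate stall the loop falls back permanently to Bland's
# smallest-index rule, which cannot cycle.
simplex_phase <- function(TT, basis, d, blocked, max_iter) {
  m_rows <- nrow(TT)
  N <- ncol(TT) - 1L
  rhs_col <- N + 1L
  bland <- FALSE
  stall <- 0L
  last_obj <- Inf
  for (iter in seq_len(max_iter)) {
    # reduced costs r_j = d_j - sum_i d[basis[i]] * T[i, j]
    db <- d[basis]
    active <- which(db != 0)
    r <- d[seq_len(N)]
    if (length(active)) {
      r <- r - colSums(TT[active, seq_len(N), drop = FALSE] * db[active])
    }
    r[blocked] <- Inf
    enter <- which(r < -LP_TOL)
    if (!length(enter)) {
      return(list(TT = TT, basis = basis, status = "optimal", iters = iter))
    }
    obj_now <- sum(db * TT[, rhs_col])
    if (obj_now < last_obj - LP_TOL) {
      stall <- 0L
      last_obj <- obj_now
    } else {
      stall <- stall + 1L
      if (stall > 50L) bland <- TRUE
    }
    j <- if (bland) enter[1L] else enter[which.min(r[enter])]
    col <- TT[, j]
    pos <- which(col > LP_TOL)
    if (!length(pos)) {
      return(list(TT = TT, basis = basis, status = "unbounded"))
    }
    ratio <- TT[pos, rhs_col] / col[pos]
    best <- min(ratio)
    cand <- pos[ratio <= best + LP_TOL]
    i <- cand[which.min(basis[cand])]  # tie-break on basis index
    # pivot on (i, j)
    piv <- TT[i, j]
    TT[i, ] <- TT[i, ] / piv
    other <- setdiff(seq_len(m_rows), i)
    fac <- TT[other, j]
    nz <- other[abs(fac) > 0]
    if (length(nz)) {
      TT[nz, ] <- TT[nz, ] - outer(TT[nz, j], TT[i, ])
    }
    TT[, j] <- 0; TT[i, j] <- 1  # kill round-off in the pivot column
    basis[i] <- j
  }
  list(TT = TT, basis = basis, status = "iteration_limit")
}

# optimise obj'v s.t. S v = 0, lb <= v <= ub
solve_lp <- function(S, lb, ub, obj, maximize = TRUE) {
  n <- ncol(S)
  m <- nrow(S)
  stopifnot(length(lb) == n, length(ub) == n, length(obj) == n,
            all(is.finite(lb)), all(is.finite(ub)))
  if (any(ub < lb)) stop("LP: some upper bound below lower bound",
                         call. = FALSE)
  u <- ub - lb
  b <- as.numeric(-S %*% lb)
  A <- S
  flip <- b < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    b[flip] <- -b[flip]
  }
  # columns: x (n) | bound slacks s (n) | artificials a (m) | RHS
  N <- 2L * n + m
  m_rows <- m + n
  TT <- matrix(0, m_rows, N + 1L)
  TT[seq_len(m), seq_len(n)] <- A
  TT[seq_len(m), 2L * n + seq_len(m)] <- diag(m)
  TT[seq_len(m), N + 1L] <- b
  TT[m + seq_len(n), seq_len(n)] <- diag(n)
  TT[m + seq_len(n), n + seq_len(n)] <- diag(n)
  TT[m + seq_len(n), N + 1L] <- u
  basis <- c(2L * n + seq_len(m), n + seq_len(n))

  max_iter <- 5000L + 200L * m_rows
  # phase 1: drive artificials out
  d1 <- c(rep(0, 2L * n), rep(1, m))
  ph1 <- simplex_phase(TT, basis, d1, blocked = integer(0),
                       max_iter = max_iter)
  if (ph1$status != "optimal") {
    return(list(status = "solver_failure", x = NULL, objective = NA_real_))
  }
  art_cols <- 2L * n + seq_len(m)
  infeas <- sum(ph1$TT[ph1$basis %in% art_cols, N + 1L])
  if (infeas > 1e-7) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  # drive any artificial still basic (at zero) out of the basis, so later
  # pivots cannot silently re-violate its equality row; a row with no
  # non-artificial entries is redundant and can keep its zero artificial
  for (i in which(ph1$basis %in% art_cols)) {
    row <- ph1$TT[i, seq_len(2L * n)]
    j <- which(abs(row) > LP_TOL)
    if (length(j)) {
      j <- j[1L]
      piv <- ph1$TT[i, j]
      ph1$TT[i, ] <- ph1$TT[i, ] / piv
      other <- setdiff(seq_len(nrow(ph1$TT)), i)
      nz <- other[abs(ph1$TT[other, j]) > 0]
      if (length(nz)) {
        ph1$TT[nz, ] <- ph1$TT[nz, ] - outer(ph1$TT[nz, j], ph1$TT[i, ])
      }
      ph1$TT[, j] <- 0; ph1$TT[i, j] <- 1
      ph1$basis[i] <- j
    }
  }
  # phase 2: original objective on the shifted variables, artificials blocked
  d2 <- c(if (maximize) -obj else obj, rep(0, n + m))
  ph2 <- simplex_phase(ph1$TT, ph1$basis, d2, blocked = art_cols,
                       max_iter = max_iter)
  if (ph2$status != "optimal") {
    return(list(status = "solver_failure", x = NULL, objective = NA_real_))
  }
  x_shift <- numeric(n)
  in_x <- which(ph2$basis <= n)
  x_shift[ph2$basis[in_x]] <- ph2$TT[in_x, N + 1L]
  v <- x_shift + lb
  resid <- max(abs(S %*% v))
  if (resid > LP_RESIDUAL_TOL) {
    return(list(status = "solver_failure", x = v, objective = NA_real_,
                residual = resid))
  }
  list(status = "optimal", x = v, objective = sum(obj * v), residual = resid)
}
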