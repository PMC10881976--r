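# Bounded-variable two-phase revised simplex.
#
# Solves  max/min c'x  s.t.  A x = b,  lb <= x <= ub  (all bounds finite).
#
# Written for the LP sizes of stoichiometric core models (tens to a few
# hundred reactions). Design favours robustness over speed: the basis system
# is re-solved exactly at every iteration (no accumulated inverse updates)
# and Bland's smallest-index rule is used throughout, which precludes
# cycling. Feasibility and optimality tolerances are 1e-9 (envelope
# differences of interest are at the 1e-3 g/g scale).

simplex_box <- function(A, b, cost, lb, ub, sense = c("max", "min"),
                        tol = 1e-9, max_iter = 50000L) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(cost) == n,
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    abort("simplex_box requires finite bounds")
  }
  if (any(lb > ub)) return(list(status = "infeasible", x = NULL,
                                value = NA_real_))
  if (sense == "min") cost <- -cost

  # augment with m artificial columns signed so their start values are >= 0
  x <- lb                                  # structural vars start at lb
  r <- b - as.numeric(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  Aa <- cbind(A, diag(sgn, m))
  N <- n + m
  lb_a <- c(lb, rep(0, m))
  ub_a <- c(ub, abs(r) + 1)                # artificials never need to grow
  x <- c(x, abs(r))
  basis <- n + seq_len(m)
  at_ub <- rep(FALSE, N)                   # nonbasic position flag

  run_phase <- function(cvec, x, basis, at_ub, iter_budget) {
    for (it in seq_len(iter_budget)) {
      B <- Aa[, basis, drop = FALSE]
      nonbasic <- setdiff(seq_len(N), basis)
      # exact basic values for the current nonbasic assignment
      xN <- ifelse(at_ub[nonbasic], ub_a[nonbasic], lb_a[nonbasic])
      x[nonbasic] <- xN
      rhs <- b - as.numeric(Aa[, nonbasic, drop = FALSE] %*% xN)
      xB <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(xB)) return(list(ok = FALSE))
      x[basis] <- xB
      y <- tryCatch(solve(t(B), cvec[basis]), error = function(e) NULL)
      if (is.null(y)) return(list(ok = FALSE))
      d <- cvec - as.numeric(crossprod(Aa, y))  # reduced costs
      dtol <- tol * (1 + max(abs(cvec)))
      improving <- nonbasic[(!at_ub[nonbasic] & d[nonbasic] > dtol) |
                            (at_ub[nonbasic] & d[nonbasic] < -dtol)]
      if (!length(improving)) {
        return(list(ok = TRUE, x = x, basis = basis, at_ub = at_ub,
                    optimal = TRUE))
      }
      j <- min(improving)                  # Bland's rule
      dirj <- if (at_ub[j]) -1 else 1      # entering variable moves this way
      w <- solve(B, Aa[, j]) * dirj        # xB changes by -w per unit step
      # ratio test: keep basic vars inside their bounds, allow bound flip
      step <- ub_a[j] - lb_a[j]
      leave <- 0L                          # 0 => bound flip
      leave_to_ub <- FALSE
      for (i in seq_len(m)) {
        if (w[i] > tol) {                  # basic i decreases toward its lb
          s <- (x[basis[i]] - lb_a[basis[i]]) / w[i]
          to_ub <- FALSE
        } else if (w[i] < -tol) {          # basic i increases toward its ub
          s <- (x[basis[i]] - ub_a[basis[i]]) / w[i]
          to_ub <- TRUE
        } else next
        s <- max(s, 0)
        eps <- tol * max(1, abs(step))
        if (s < step - eps ||
            (s <= step + eps && leave > 0L && basis[i] < basis[leave])) {
          # strictly smaller ratio, or Bland smallest-index tie-break
          step <- min(s, step); leave <- i; leave_to_ub <- to_ub
        }
      }
      if (!is.finite(step)) return(list(ok = FALSE))  # cannot occur: finite bounds
      if (leave == 0L) {                   # bound flip, basis unchanged
        at_ub[j] <- !at_ub[j]
      } else {
        out_var <- basis[leave]
        basis[leave] <- j
        at_ub[out_var] <- leave_to_ub
        at_ub[j] <- FALSE
      }
    }
    list(ok = FALSE)                       # iteration budget exhausted
  }

  # phase 1: drive the artificials to zero
  c1 <- c(rep(0, n), rep(-1, m))
  p1 <- run_phase(c1, x, basis, at_ub, max_iter)
  if (!p1$ok) return(list(status = "failed", x = NULL, value = NA_real_))
  art_sum <- sum(p1$x[n + seq_len(m)])
  if (art_sum > 1e-7 * max(1, max(abs(b)))) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  # pin artificials at zero for phase 2
  ub_a[n + seq_len(m)] <- 0
  x <- p1$x; x[n + seq_len(m)] <- 0
  c2 <- c(cost, rep(0, m))
  p2 <- run_phase(c2, x, p1$basis, p1$at_ub, max_iter)
  if (!p2$ok) return(list(status = "failed", x = NULL, value = NA_real_))
  xs <- p2$x[seq_len(n)]
  value <- sum(cost * xs)
  list(status = "optimal", x = xs,
       value = if (sense == "min") -value else value)
}
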