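## Fallback dense two-phase simplex with Bland's anti-cycling rule.
## The primary LP path is boot::simplex; on rare degenerate problems its
## pivoting produces NaN and aborts, so solve_lp() retries with this
## implementation, which trades speed for unconditional termination.
##
## Solves: optimize a'x  s.t.  A1 x <= b1, A2 x >= b2, A3 x = b3, x >= 0,
## with all b >= 0. Returns list(solved, soln, value) in the same shape
## as boot::simplex (solved: 1 optimal, -1 infeasible, 0 unbounded).

simplex_two_phase <- function(a, A1 = NULL, b1 = NULL, A2 = NULL, b2 = NULL,
                              A3 = NULL, b3 = NULL, maxi = FALSE,
                              tol = 1e-9) {
  n <- length(a)
  obj <- if (maxi) a else -a          # internally always maximize
  rows <- list(); rhs <- numeric(0); type <- character(0)
  add <- function(A, b, ty) {
    if (!is.null(A) && nrow(A) > 0) {
      rows[[length(rows) + 1L]] <<- A
      rhs <<- c(rhs, b)
      type <<- c(type, rep(ty, nrow(A)))
    }
  }
  add(A1, b1, "le"); add(A2, b2, "ge"); add(A3, b3, "eq")
  A <- do.call(rbind, rows)
  m <- nrow(A)
  n_slack <- sum(type == "le")
  n_surp <- sum(type == "ge")
  n_art <- sum(type != "le")
  N <- n + n_slack + n_surp + n_art
  Tb <- matrix(0, m, N)
  Tb[, seq_len(n)] <- A
  basis <- integer(m)
  si <- 0L; ui <- 0L; ai <- 0L
  for (i in seq_len(m)) {
    if (type[i] == "le") {
      si <- si + 1L
      Tb[i, n + si] <- 1
      basis[i] <- n + si
    } else {
      if (type[i] == "ge") {
        ui <- ui + 1L
        Tb[i, n + n_slack + ui] <- -1
      }
      ai <- ai + 1L
      Tb[i, n + n_slack + n_surp + ai] <- 1
      basis[i] <- n + n_slack + n_surp + ai
    }
  }
  b <- rhs
  art_cols <- if (n_art) (n + n_slack + n_surp) + seq_len(n_art) else integer(0)

  pivot <- function(Tb, b, z, r, c) {
    pv <- Tb[r, c]
    Tb[r, ] <- Tb[r, ] / pv
    b[r] <- b[r] / pv
    for (i in seq_len(nrow(Tb))) if (i != r && abs(Tb[i, c]) > 0) {
      f <- Tb[i, c]
      Tb[i, ] <- Tb[i, ] - f * Tb[r, ]
      b[i] <- b[i] - f * b[r]
    }
    f <- z[c]
    z <- z - f * Tb[r, ]
    list(Tb = Tb, b = b, z = z)
  }

  run_phase <- function(Tb, b, basis, cost, allowed) {
    ## reduced costs z for maximizing cost'x: z_j = cost_j - cB' B^-1 A_j
    z <- cost
    for (i in seq_len(m)) if (cost[basis[i]] != 0)
      z <- z - cost[basis[i]] * Tb[i, ]
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > 20000L) return(NULL)
      enter <- 0L
      for (j in allowed) if (z[j] > tol) { enter <- j; break }  # Bland
      if (enter == 0L) return(list(Tb = Tb, b = b, basis = basis, z = z))
      ratios <- ifelse(Tb[, enter] > tol, b / Tb[, enter], Inf)
      if (all(is.infinite(ratios))) return("unbounded")
      rmin <- min(ratios)
      cand <- which(abs(ratios - rmin) <= tol * max(1, rmin))
      leave <- cand[which.min(basis[cand])]                     # Bland
      res <- pivot(Tb, b, z, leave, enter)
      Tb <- res$Tb; b <- res$b; z <- res$z
      basis[leave] <- enter
    }
  }

  if (n_art) {
    cost1 <- numeric(N); cost1[art_cols] <- -1
    ph1 <- run_phase(Tb, b, basis, cost1, seq_len(N))
    if (is.null(ph1) || identical(ph1, "unbounded"))
      return(list(solved = -1, soln = rep(NA_real_, n), value = NA_real_))
    obj1 <- sum(ph1$b[ph1$basis %in% art_cols])
    if (obj1 > 1e-7)
      return(list(solved = -1, soln = rep(NA_real_, n), value = NA_real_))
    Tb <- ph1$Tb; b <- ph1$b; basis <- ph1$basis
    ## drive any residual (degenerate) artificials out of the basis
    for (i in seq_len(m)) {
      if (basis[i] %in% art_cols) {
        j <- which(abs(Tb[i, seq_len(n + n_slack + n_surp)]) > tol)[1]
        if (!is.na(j)) {
          res <- pivot(Tb, b, numeric(N), i, j)
          Tb <- res$Tb; b <- res$b
          basis[i] <- j
        }
      }
    }
  }
  cost2 <- numeric(N); cost2[seq_len(n)] <- obj
  allowed <- setdiff(seq_len(N), art_cols)
  ph2 <- run_phase(Tb, b, basis, cost2, allowed)
  if (is.null(ph2))
    return(list(solved = 0, soln = rep(NA_real_, n), value = NA_real_))
  if (identical(ph2, "unbounded"))
    return(list(solved = 0, soln = rep(NA_real_, n), value = NA_real_))
  x <- numeric(N)
  x[ph2$basis] <- ph2$b
  soln <- x[seq_len(n)]
  list(solved = 1, soln = soln, value = sum(a * soln))
}
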