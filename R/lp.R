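## Linear programming core.
##
## All constraint-based analyses in this package reduce to LPs of the form
##   min/max  c'x   s.t.  A x = b,  l <= x <= u
## Problems are small (tens to hundreds of variables), so a dense two-phase
## bounded-variable revised simplex with Bland's rule is used: fully
## deterministic, no external solver dependency. `boot::simplex` is wrapped
## as an independent second backend for cross-checking.

LP_FEAS_TOL <- 1e-9
LP_OPT_TOL <- 1e-9

#' Solve a bounded linear program
#'
#' Minimises (or maximises) `obj %*% x` subject to `A %*% x == rhs` and
#' `lb <= x <= ub`. Used internally by all flux-balance computations.
#'
#' @param obj numeric objective coefficients.
#' @param A dense or sparse constraint matrix (equality constraints).
#' @param rhs right-hand side vector.
#' @param lb,ub variable bounds (finite values recommended; `Inf` allowed).
#' @param maximize logical; maximise instead of minimise.
#' @param backend `"simplex"` (internal), `"scipy"` (scipy's HiGHS solver
#'   through a Python subprocess; shares no code with the internal simplex,
#'   used for cross-validation), or `"boot"` (`boot::simplex`; suitable for
#'   small problems only).
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x`, and `objective` (on the original max/min scale).
#' @keywords internal
lp_solve <- function(obj, A, rhs, lb, ub, maximize = FALSE,
                     backend = c("simplex", "scipy", "boot")) {
  backend <- match.arg(backend)
  A <- as.matrix(A)
  stopifnot(length(obj) == ncol(A), length(rhs) == nrow(A),
            length(lb) == ncol(A), length(ub) == ncol(A))
  if (any(lb > ub + LP_FEAS_TOL)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  cc <- if (maximize) -obj else obj
  res <- switch(backend,
    simplex = lp_simplex(cc, A, rhs, lb, ub),
    scipy = lp_scipy(cc, A, rhs, lb, ub),
    boot = lp_boot(cc, A, rhs, lb, ub)
  )
  if (res$status == "optimal" && maximize) res$objective <- -res$objective
  res
}

## Internal bounded-variable two-phase simplex, Bland's rule throughout.
lp_simplex <- function(cc, A, b, lb, ub) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {
    ## pure bound problem
    x <- ifelse(cc >= 0, lb, ub)
    x[!is.finite(x)] <- 0
    if (any(!is.finite(x) | x < lb - LP_FEAS_TOL | x > ub + LP_FEAS_TOL))
      return(list(status = "unbounded", x = NULL, objective = NA_real_))
    return(list(status = "optimal", x = x, objective = sum(cc * x)))
  }

  ## initial nonbasic values: bound closest to zero (deterministic)
  start_val <- function(l, u) {
    if (is.finite(l) && l >= 0) return(l)
    if (is.finite(u) && u <= 0) return(u)
    if (is.finite(l) && is.finite(u)) return(if (abs(l) <= abs(u)) l else u)
    if (is.finite(l)) return(l)
    if (is.finite(u)) return(u)
    0
  }
  xval <- mapply(start_val, lb, ub)
  at_upper <- is.finite(ub) & abs(xval - ub) <= abs(xval - ifelse(is.finite(lb), lb, Inf))
  at_upper[is.finite(lb) & xval == lb] <- FALSE

  resid <- b - as.vector(A %*% xval)
  ## artificial columns
  Aa <- cbind(A, diag(ifelse(resid >= 0, 1, -1), m))
  lb2 <- c(lb, rep(0, m)); ub2 <- c(ub, rep(Inf, m))
  xval <- c(xval, abs(resid))
  basis <- (n + 1L):(n + m)
  nonbasic_upper <- c(at_upper, rep(FALSE, m))

  run_phase <- function(costs, basis, xval, nonbasic_upper, lbv, ubv) {
    maxit <- 5000L + 200L * (n + m)
    for (it in seq_len(maxit)) {
      B <- Aa[, basis, drop = FALSE]
      Binv_ok <- TRUE
      y <- tryCatch(solve(t(B), costs[basis]), error = function(e) {Binv_ok <<- FALSE; NULL})
      if (!Binv_ok) return(list(status = "singular"))
      nonbasic <- setdiff(seq_len(n + m), basis)
      d <- costs[nonbasic] - as.vector(t(Aa[, nonbasic, drop = FALSE]) %*% y)
      improving <- (!nonbasic_upper[nonbasic] & d < -LP_OPT_TOL) |
                   ( nonbasic_upper[nonbasic] & d >  LP_OPT_TOL)
      ## fixed variables (lb == ub) can never improve
      improving <- improving & (ubv[nonbasic] - lbv[nonbasic] > LP_FEAS_TOL)
      if (!any(improving)) {
        return(list(status = "optimal", basis = basis, xval = xval,
                    nonbasic_upper = nonbasic_upper))
      }
      e <- min(nonbasic[improving])                 # Bland: smallest index
      dir <- if (nonbasic_upper[e]) -1 else 1       # increase from lb / decrease from ub
      w <- as.vector(solve(B, Aa[, e]))             # x_B changes by -dir*w*delta
      ## ratio test
      delta <- ubv[e] - lbv[e]                      # bound flip distance
  leave <- 0L; leave_to_upper <- FALSE
      for (k in seq_len(m)) {
        bi <- basis[k]
        chg <- -dir * w[k]
        if (chg < -LP_FEAS_TOL) {                   # basic decreasing, hits lb
          if (is.finite(lbv[bi])) {
            r <- (xval[bi] - lbv[bi]) / (-chg)
            if (r < delta - LP_FEAS_TOL || (r < delta + LP_FEAS_TOL && leave != 0L && bi < basis[leave])) {
              delta <- max(r, 0); leave <- k; leave_to_upper <- FALSE
            }
          }
        } else if (chg > LP_FEAS_TOL) {             # basic increasing, hits ub
          if (is.finite(ubv[bi])) {
            r <- (ubv[bi] - xval[bi]) / chg
            if (r < delta - LP_FEAS_TOL || (r < delta + LP_FEAS_TOL && leave != 0L && bi < basis[leave])) {
              delta <- max(r, 0); leave <- k; leave_to_upper <- TRUE
            }
          }
        }
      }
      if (!is.finite(delta)) return(list(status = "unbounded"))
      ## apply step
      xval[e] <- xval[e] + dir * delta
      xval[basis] <- xval[basis] - dir * w * delta
      if (leave == 0L) {                            # bound flip, basis unchanged
        nonbasic_upper[e] <- !nonbasic_upper[e]
      } else {
        bi <- basis[leave]
        xval[bi] <- if (leave_to_upper) ubv[bi] else lbv[bi]  # snap exactly
        nonbasic_upper[bi] <- leave_to_upper
        basis[leave] <- e
      }
    }
    list(status = "maxiter")
  }

  ## phase 1: minimise sum of artificials
  c1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(c1, basis, xval, nonbasic_upper, lb2, ub2)
  if (ph1$status != "optimal") {
    return(list(status = if (ph1$status == "unbounded") "infeasible" else "error",
                x = NULL, objective = NA_real_))
  }
  art <- (n + 1L):(n + m)
  if (sum(ph1$xval[art]) > 1e-7) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  ## pin artificials to zero and run phase 2 with real costs
  ub2[art] <- 0
  ph1$xval[art] <- 0
  c2 <- c(cc, rep(0, m))
  ph2 <- run_phase(c2, ph1$basis, ph1$xval, ph1$nonbasic_upper, lb2, ub2)
  if (ph2$status != "optimal") {
    st <- if (ph2$status == "unbounded") "unbounded" else "error"
    return(list(status = st, x = NULL, objective = NA_real_))
  }
  x <- ph2$xval[seq_len(n)]
  list(status = "optimal", x = x, objective = sum(cc * x))
}

## scipy HiGHS backend via a Python subprocess and JSON exchange
lp_scipy <- function(cc, A, b, lb, ub) {
  script <- system.file("python", "lp_solve.py", package = "cyanoflux")
  py <- Sys.which("python")
  if (!nzchar(py) || !nzchar(script)) {
    stop("scipy backend needs a python interpreter on the PATH")
  }
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(
    list(c = cc, A = as.vector(t(A)), b = b,
         lb = ifelse(is.finite(lb), lb, -1e30),
         ub = ifelse(is.finite(ub), ub, 1e30)),
    fin, digits = NA)
  rc <- system2(py, c(script, fin, fout), stdout = FALSE, stderr = FALSE)
  if (rc != 0L || !file.exists(fout)) {
    stop("scipy LP backend failed (exit ", rc, ")")
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)
  if (!identical(res$status, "optimal")) {
    return(list(status = res$status, x = NULL, objective = NA_real_))
  }
  list(status = "optimal", x = as.numeric(res$x),
       objective = as.numeric(res$objective))
}

## boot::simplex backend: shift x = v - lb >= 0, finite bounds required.
lp_boot <- function(cc, A, b, lb, ub) {
  if (!requireNamespace("boot", quietly = TRUE)) {
    stop("backend 'boot' requires the boot package")
  }
  big <- 1e6
  lbf <- ifelse(is.finite(lb), lb, -big)
  ubf <- ifelse(is.finite(ub), ub, big)
  n <- ncol(A)
  b3 <- b - as.vector(A %*% lbf)
  A3 <- A
  neg <- b3 < 0
  A3[neg, ] <- -A3[neg, , drop = FALSE]
  b3[neg] <- -b3[neg]
  res <- tryCatch(
    boot::simplex(a = cc, A1 = diag(n), b1 = ubf - lbf, A3 = A3, b3 = b3,
                  maxi = FALSE, n.iter = n + 5 * nrow(A) + 2000, eps = 1e-10),
    error = function(e) NULL
  )
  if (is.null(res) || res$solved != 1) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  x <- as.vector(res$soln) + lbf
  list(status = "optimal", x = x, objective = sum(cc * x))
}
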