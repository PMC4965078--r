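#' Stationary mRNA distribution from the truncated master equation
#'
#' Solves the chemical master equation of the two-state model on the state
#' space (promoter in {OFF, ON}) x (mRNA in 0..N_max) for its stationary
#' distribution, marginalized over the promoter. Serves as a numerically
#' exact oracle for the stochastic simulator and the moment formulas.
#'
#' The truncation `N_max` starts at `mean + 10 sd` (from
#' [analytic_mrna_moments()]) and doubles until the probability stranded at
#' the reflecting boundary falls below `tol / 10`, so the neglected tail
#' mass is below `tol`.
#'
#' @param params a [telegraph_params()] object with `d_m > 0`.
#' @param tol permitted truncation mass in the neglected tail.
#' @param max_doublings growth cap for the adaptive truncation; exceeding it
#'   raises an error.
#' @return An object of class `stationary_distribution`: list with `support`
#'   (0..N_max), `probability`, `n_max` and `params`.
#' @examples
#' d <- stationary_distribution(telegraph_params(1, 50, 250))
#' sum(d$support * d$probability)  # matches the analytic mean
#' @export
stationary_distribution <- function(params, tol = 1e-8, max_doublings = 6) {
  stopifnot(inherits(params, "telegraph_params"))
  if (params$d_m <= 0)
    stop("d_m must be > 0 for a stationary distribution", call. = FALSE)
  if (params$T == 0) {
    out <- list(support = 0L, probability = 1, n_max = 0L, params = params)
    return(structure(out, class = "stationary_distribution"))
  }
  if (params$k_on == 0) {   # promoter can never switch ON from the OFF start
    mom <- list(mean = 0)
  } else {
    mom <- analytic_mrna_moments(params)
  }
  ks <- params$k_on + params$k_off
  vr <- if (params$k_on > 0)
    mom$mean * (1 + params$T * params$k_off / (ks * (ks + params$d_m)))
  else 0
  n_max <- max(20L, as.integer(ceiling(mom$mean + 10 * sqrt(max(vr, 1)))))
  for (i in seq_len(max_doublings + 1L)) {
    pr <- .cme_solve(params, n_max)
    boundary_mass <- sum(pr[length(pr)])
    if (boundary_mass < tol / 10) {
      out <- list(support = 0:n_max, probability = pr,
                  n_max = n_max, params = params)
      return(structure(out, class = "stationary_distribution"))
    }
    n_max <- n_max * 2L
  }
  stop("master-equation truncation failed to converge below tol within ",
       max_doublings, " doublings", call. = FALSE)
}

# Sparse generator over states idx(g, m) = g * (N+1) + m + 1, solved for the
# stationary vector by replacing one balance equation with normalization.
.cme_solve <- function(params, n_max) {
  n <- n_max + 1L
  nstates <- 2L * n
  idx <- function(g, m) g * n + m + 1L
  m_all <- 0:n_max

  from <- integer(0); to <- integer(0); rate <- numeric(0)
  add <- function(i, j, r) {
    keep <- r > 0
    from <<- c(from, i[keep]); to <<- c(to, j[keep]); rate <<- c(rate, r[keep])
  }
  # promoter switching
  add(idx(0L, m_all), idx(1L, m_all), rep(params$k_on, n))
  add(idx(1L, m_all), idx(0L, m_all), rep(params$k_off, n))
  # transcription while ON (reflecting at m = n_max)
  if (n_max >= 1)
    add(idx(1L, 0:(n_max - 1L)), idx(1L, 1:n_max), rep(params$T, n_max))
  # degradation
  if (n_max >= 1) {
    add(idx(0L, 1:n_max), idx(0L, 0:(n_max - 1L)), params$d_m * (1:n_max))
    add(idx(1L, 1:n_max), idx(1L, 0:(n_max - 1L)), params$d_m * (1:n_max))
  }

  Q <- Matrix::sparseMatrix(i = from, j = to, x = rate,
                            dims = c(nstates, nstates))
  Q <- Q - Matrix::Diagonal(x = Matrix::rowSums(Q))
  A <- Matrix::t(Q)
  A[nstates, ] <- 1                      # normalization replaces one equation
  b <- c(rep(0, nstates - 1L), 1)
  pi_full <- as.numeric(Matrix::solve(A, b))
  pi_full[pi_full < 0 & pi_full > -1e-12] <- 0
  pr <- pi_full[idx(0L, m_all)] + pi_full[idx(1L, m_all)]
  pr / sum(pr)
}

#' @export
print.stationary_distribution <- function(x, ...) {
  mom <- dist_moments(x)
  cat(sprintf(
    "stationary mRNA distribution on 0..%d: mean %.4g, Fano %.4g\n",
    x$n_max, mom$mean, mom$fano))
  invisible(x)
}

#' Moments of a stationary distribution object
#'
#' @param dist a [stationary_distribution()] object.
#' @return List with `mean`, `variance`, `fano` (NA when the mean is 0).
#' @export
dist_moments <- function(dist) {
  stopifnot(inherits(dist, "stationary_distribution"))
  m1 <- sum(dist$support * dist$probability)
  m2 <- sum(dist$support^2 * dist$probability)
  v <- m2 - m1^2
  list(mean = m1, variance = v,
       fano = if (m1 > 0) v / m1 else NA_real_)
}
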