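#' Exact stochastic simulation of the telegraph model
#'
#' Gillespie (direct-method) realization of the reaction network
#' `{OFF->ON (k_on), ON->OFF (k_off), 0->mRNA (T while ON), mRNA->0 (d_m m),
#' mRNA->mRNA+protein (L m), protein->0 (d_p p)}`. The protein stage is
#' simulated only when `record_protein = TRUE`; mRNA-level analyses do not
#' need it and skipping it saves most of the event budget.
#'
#' Randomness comes from R's global generator: calling with the same `seed`
#' (or the same prior `set.seed()`) reproduces the trajectory exactly.
#'
#' @param params a [telegraph_params()] object.
#' @param t_end simulation end time (> 0), in the same units as the rates.
#' @param seed optional integer; when supplied, `set.seed(seed)` is called
#'   first so the realization is reproducible.
#' @param record_protein simulate the translation/protein-decay reactions.
#' @param init named list of initial state, elements `promoter` (0/1),
#'   `mrna`, `protein`; defaults to all zero.
#' @return An object of class `telegraph_trajectory`: list with `times`
#'   (event times, starting at 0), `promoter_state`, `mrna_count`,
#'   `protein_count` (state on the interval starting at each time) and
#'   `t_end`.
#' @examples
#' tr <- simulate_ssa(telegraph_params(1, 10, 50), t_end = 5, seed = 7)
#' max(tr$mrna_count)
#' @export
simulate_ssa <- function(params, t_end, seed = NULL, record_protein = FALSE,
                         init = list(promoter = 0L, mrna = 0, protein = 0)) {
  stopifnot(inherits(params, "telegraph_params"))
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0)
    stop("t_end must be a single positive number", call. = FALSE)
  .check_reactions_possible(params, record_protein)
  if (!is.null(seed)) set.seed(seed)
  g0 <- as.integer(init$promoter %||% 0L)
  m0 <- as.numeric(init$mrna %||% 0)
  p0 <- as.numeric(init$protein %||% 0)
  out <- .ssa_trajectory_cpp(params$k_on, params$k_off, params$T, params$L,
                             params$d_m, params$d_p, t_end,
                             g0, m0, p0, isTRUE(record_protein))
  structure(out, class = "telegraph_trajectory", params = params)
}

#' @export
print.telegraph_trajectory <- function(x, ...) {
  cat(sprintf("telegraph SSA trajectory: %d events over t in [0, %g]\n",
              length(x$times) - 1L, x$t_end))
  cat(sprintf("  final state: promoter %d, mRNA %g, protein %g\n",
              x$promoter_state[length(x$promoter_state)],
              x$mrna_count[length(x$mrna_count)],
              x$protein_count[length(x$protein_count)]))
  invisible(x)
}

#' Draw independent cells from the stationary state
#'
#' Simulates `n_cells` independent trajectories from the zero state for a
#' burn-in of `burnin_mult` times the slowest system timescale
#' (`max(1/d_m, 1/d_p, 1/(k_on + k_off))`, protein timescale only when
#' simulated) and returns the end states. With the default ten-lifetime
#' burn-in the initial condition is forgotten to well below sampling error.
#'
#' @inheritParams simulate_ssa
#' @param n_cells number of independent cells (>= 1).
#' @param burnin_mult burn-in length in multiples of the slowest timescale.
#' @return A data.frame with columns `cell`, `mrna` and (if
#'   `record_protein`) `protein`.
#' @examples
#' cells <- sample_steady_state(telegraph_params(1, 50, 250), 500, seed = 1)
#' mean(cells$mrna)  # close to 250/51
#' @export
sample_steady_state <- function(params, n_cells, seed = NULL,
                                record_protein = FALSE, burnin_mult = 10) {
  stopifnot(inherits(params, "telegraph_params"))
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1)
    stop("n_cells must be a positive integer", call. = FALSE)
  .check_reactions_possible(params, record_protein)
  if (!is.null(seed)) set.seed(seed)
  t_burn <- burnin_mult * .slowest_timescale(params, record_protein)
  st <- .ssa_endstate_cpp(params$k_on, params$k_off, params$T, params$L,
                          params$d_m, params$d_p, t_burn,
                          as.integer(n_cells), isTRUE(record_protein))
  out <- data.frame(cell = seq_len(nrow(st)), mrna = st[, 1])
  if (record_protein) out$protein <- st[, 2]
  out
}

.slowest_timescale <- function(params, record_protein) {
  ts <- c()
  if (params$d_m > 0) ts <- c(ts, 1 / params$d_m)
  if (record_protein && params$d_p > 0) ts <- c(ts, 1 / params$d_p)
  if (params$k_on + params$k_off > 0) ts <- c(ts, 1 / (params$k_on + params$k_off))
  if (!length(ts))
    stop("no finite relaxation timescale (all relevant rates zero)",
         call. = FALSE)
  max(ts)
}

.check_reactions_possible <- function(params, record_protein) {
  rates <- c(params$k_on, params$k_off, params$T, params$d_m)
  if (record_protein) rates <- c(rates, params$L, params$d_p)
  if (all(rates == 0))
    stop("all rates are zero: no reactions possible", call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
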