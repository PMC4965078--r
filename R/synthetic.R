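#' Configuration of a synthetic isoclonal reporter panel
#'
#' Describes a panel of clonal populations, each expressing a reporter from
#' one genomic integration site with its own transcriptional burst size `b`
#' and burst frequency `f` (drawn log-uniformly from the configured ranges,
#' matching the order-of-magnitude spread seen across integration sites).
#' The generator emulates the two readouts of such panels:
#'
#' * an smFISH-like table of per-cell mRNA molecule counts, and
#' * a flow-cytometry-like table of per-event scatter plus fluorescence in
#'   MESF units, where fluorescence = protein copies x `mesf_per_protein`
#'   x a lognormal extrinsic factor (CV `extrinsic_cv`), plus an additive
#'   Gaussian autofluorescence background clipped at zero. The same
#'   extrinsic factor scales the scatter channels, so a tight scatter
#'   sub-gate ([subgate()]) removes extrinsic variability.
#'
#' The protein stage uses translation rate `l_rate` and protein decay
#' `d_p`; with the defaults `l_rate = 5`, `d_p = d_m = 1` and
#' `mesf_per_protein = 2000`, one burst unit corresponds to
#' `mesf_per_protein * l_rate / (d_m + d_p) = 5000` MESF — the calibration
#' constant of the MESF burst-size formula ([burst_size_mesf()]).
#'
#' @param n_clones number of clones (default 30).
#' @param burst_size_range range of kinetic burst sizes `b = T/k_off`
#'   (default 2-12 mRNAs).
#' @param burst_freq_range range of burst frequencies in units of `d_m`
#'   (default 0.05-2 per mRNA lifetime).
#' @param n_cells_fish cells per clone in the smFISH table (default 150;
#'   imaging yields upwards of 100 cells per condition).
#' @param n_events_flow flow events recorded per clone (default 50000).
#' @param extrinsic_cv CV of the lognormal extrinsic factor (default 0.3).
#' @param autofluorescence_mean,autofluorescence_sd additive background in
#'   MESF units (defaults 500 and 100).
#' @param mesf_per_protein MESF units per protein molecule (default 2000).
#' @param l_rate,d_p,d_m protein-stage and mRNA kinetics (see Details).
#' @param seed integer seed driving every random choice of the generator.
#' @return An object of class `clone_panel_config`.
#' @export
clone_panel_config <- function(n_clones = 30,
                               burst_size_range = c(2, 12),
                               burst_freq_range = c(0.05, 2),
                               n_cells_fish = 150,
                               n_events_flow = 50000,
                               extrinsic_cv = 0.3,
                               autofluorescence_mean = 500,
                               autofluorescence_sd = 100,
                               mesf_per_protein = 2000,
                               l_rate = 5, d_p = 1, d_m = 1,
                               seed = 1) {
  stopifnot(n_clones >= 1, length(burst_size_range) == 2,
            length(burst_freq_range) == 2,
            all(burst_size_range > 0), all(burst_freq_range > 0),
            n_cells_fish >= 2, n_events_flow >= 2,
            extrinsic_cv >= 0, autofluorescence_sd >= 0,
            mesf_per_protein > 0, l_rate > 0, d_p > 0, d_m > 0)
  structure(list(n_clones = n_clones,
                 burst_size_range = sort(burst_size_range),
                 burst_freq_range = sort(burst_freq_range),
                 n_cells_fish = n_cells_fish,
                 n_events_flow = n_events_flow,
                 extrinsic_cv = extrinsic_cv,
                 autofluorescence_mean = autofluorescence_mean,
                 autofluorescence_sd = autofluorescence_sd,
                 mesf_per_protein = mesf_per_protein,
                 l_rate = l_rate, d_p = d_p, d_m = d_m,
                 seed = as.integer(seed)),
            class = "clone_panel_config")
}

#' Telegraph rates for a (burst size, burst frequency) pair
#'
#' Bursting-regime parameterization used throughout the generator:
#' `k_off = 20 d_m max(b/2, 1)` keeps promoter switching much faster than
#' mRNA turnover and `k_off >> k_on` for all configured frequencies, then
#' `T = b k_off` and `k_on = f d_m`. A warning is recorded when the regime
#' is violated (`k_off <= 10 k_on`).
#'
#' @param b kinetic burst size.
#' @param f burst frequency in units of `d_m`.
#' @param d_m mRNA degradation rate.
#' @param l_rate,d_p protein-stage rates.
#' @return A [telegraph_params()] object.
#' @export
clone_params <- function(b, f, d_m = 1, l_rate = 0, d_p = 0) {
  k_off <- 20 * d_m * max(b / 2, 1)
  k_on <- f * d_m
  if (k_off <= 10 * k_on)
    warning("bursting regime violated: k_off = ", k_off, " <= 10 k_on = ",
            10 * k_on, call. = FALSE)
  telegraph_params(k_on = k_on, k_off = k_off, T = b * k_off,
                   L = l_rate, d_m = d_m, d_p = d_p)
}

#' Generate a synthetic clone panel
#'
#' Draws per-clone (burst size, burst frequency) log-uniformly from the
#' configured ranges (or reuses a supplied `truth` table, e.g. a perturbed
#' one), simulates the telegraph model to steady state for every cell, and
#' assembles the smFISH count table and, optionally, the flow-cytometry
#' event table. All randomness descends from `cfg$seed`, so identical
#' configurations yield identical tables.
#'
#' @param cfg a [clone_panel_config()].
#' @param condition condition label stamped on the tables.
#' @param truth optional ground-truth table from a previous call (columns
#'   `clone_id`, `b`, `f`); when supplied, parameters are not redrawn.
#' @param flow simulate the protein stage and build the flow table
#'   (default TRUE); the smFISH table alone is much cheaper.
#' @return A list with:
#'   * `counts` — data.frame `clone_id`, `condition`, `cell_id`,
#'     `mrna_count`;
#'   * `flow` — data.frame `clone_id`, `condition`, `event_id`, `fsc`,
#'     `ssc`, `mesf`, plus ground-truth columns `protein` (copies) and
#'     `extrinsic` (factor) for recovery tests (dropped on CSV export);
#'   * `truth` — per-clone parameters and analytic moments.
#' @export
generate_clone_panel <- function(cfg, condition = "baseline", truth = NULL,
                                 flow = TRUE) {
  stopifnot(inherits(cfg, "clone_panel_config"))
  set.seed(cfg$seed + .condition_offset(condition))
  if (is.null(truth)) {
    b <- exp(stats::runif(cfg$n_clones, log(cfg$burst_size_range[1]),
                          log(cfg$burst_size_range[2])))
    f <- exp(stats::runif(cfg$n_clones, log(cfg$burst_freq_range[1]),
                          log(cfg$burst_freq_range[2])))
    truth <- panel_truth(b, f, cfg)
  } else if (!all(c("k_on", "k_off", "T", "d_m") %in% names(truth))) {
    truth <- panel_truth(truth$b, truth$f, cfg, clone_id = truth$clone_id)
  }   # a full truth table (e.g. a perturbed one) is used exactly as given

  counts <- vector("list", nrow(truth))
  flows <- if (flow) vector("list", nrow(truth)) else NULL
  for (i in seq_len(nrow(truth))) {
    pars <- .truth_params(truth[i, ], cfg, protein = FALSE)
    cells <- sample_steady_state(pars, cfg$n_cells_fish)
    counts[[i]] <- data.frame(clone_id = truth$clone_id[i],
                              condition = condition,
                              cell_id = seq_len(cfg$n_cells_fish),
                              mrna_count = as.integer(cells$mrna),
                              stringsAsFactors = FALSE)
    if (flow) {
      ppars <- .truth_params(truth[i, ], cfg, protein = TRUE)
      ev <- sample_steady_state(ppars, cfg$n_events_flow,
                                record_protein = TRUE)
      flows[[i]] <- .flow_events(ev$protein, truth$clone_id[i], condition, cfg)
    }
  }
  list(counts = do.call(rbind, counts),
       flow = if (flow) do.call(rbind, flows) else NULL,
       truth = truth)
}

# Distinct conditions get distinct (but seed-derived) substreams so that a
# perturbed panel is not coupled realization-by-realization to its baseline.
.condition_offset <- function(condition) {
  sum(utf8ToInt(as.character(condition))) %% 1000L
}

#' Ground-truth table for a set of (b, f) clones
#'
#' @param b,f kinetic burst sizes and frequencies, equal length.
#' @param cfg a [clone_panel_config()] providing `d_m`, `l_rate`, `d_p`.
#' @param clone_id optional identifiers (default `clone_01`, ...).
#' @return data.frame with rates and analytic stationary moments per clone.
#' @export
panel_truth <- function(b, f, cfg, clone_id = NULL) {
  stopifnot(length(b) == length(f))
  if (is.null(clone_id))
    clone_id <- sprintf("clone_%02d", seq_along(b))
  rows <- lapply(seq_along(b), function(i) {
    pars <- clone_params(b[i], f[i], d_m = cfg$d_m,
                         l_rate = cfg$l_rate, d_p = cfg$d_p)
    mom <- analytic_mrna_moments(pars)
    data.frame(clone_id = clone_id[i], b = b[i], f = f[i],
               k_on = pars$k_on, k_off = pars$k_off, T = pars$T,
               L = pars$L, d_m = pars$d_m, d_p = pars$d_p,
               analytic_mean = mom$mean, analytic_fano = mom$fano,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.truth_params <- function(row, cfg, protein) {
  telegraph_params(k_on = row$k_on, k_off = row$k_off, T = row$T,
                   L = if (protein) cfg$l_rate else 0,
                   d_m = row$d_m, d_p = if (protein) cfg$d_p else 0)
}

# Dress protein end-states as flow events: shared lognormal extrinsic factor
# on fluorescence and scatter, light multiplicative measurement noise on
# scatter, additive clipped-Gaussian autofluorescence on fluorescence.
.flow_events <- function(protein, clone_id, condition, cfg) {
  n <- length(protein)
  sdlog <- sqrt(log(1 + cfg$extrinsic_cv^2))
  e <- if (cfg$extrinsic_cv > 0)
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  else rep(1, n)
  af <- if (cfg$autofluorescence_sd > 0)
    pmax(stats::rnorm(n, cfg$autofluorescence_mean, cfg$autofluorescence_sd), 0)
  else rep(cfg$autofluorescence_mean, n)
  data.frame(clone_id = clone_id, condition = condition, event_id = seq_len(n),
             fsc = 50000 * e * exp(stats::rnorm(n, 0, 0.05)),
             ssc = 30000 * e * exp(stats::rnorm(n, 0, 0.05)),
             mesf = protein * cfg$mesf_per_protein * e + af,
             protein = protein, extrinsic = e,
             stringsAsFactors = FALSE)
}

#' Configuration of a burst-frequency perturbation
#'
#' Models an activating stimulus (TNF-like) that multiplies the promoter
#' activation rate `k_on` by `freq_fold_change` for every clone; clones
#' whose baseline analytic mean already exceeds `size_threshold_mean`
#' additionally have their transcription rate `T` multiplied by
#' `size_fold_change` — the expression-level threshold above which burst
#' size, rather than burst frequency alone, begins to change.
#'
#' @param freq_fold_change multiplier on `k_on` (default 5).
#' @param size_threshold_mean baseline mean mRNA level above which the
#'   burst-size channel engages (default 10).
#' @param size_fold_change multiplier on `T` above threshold (default 2).
#' @return An object of class `perturbation_config`.
#' @export
perturbation_config <- function(freq_fold_change = 5,
                                size_threshold_mean = 10,
                                size_fold_change = 2) {
  stopifnot(freq_fold_change > 0, size_fold_change >= 1,
            size_threshold_mean >= 0)
  structure(list(freq_fold_change = freq_fold_change,
                 size_threshold_mean = size_threshold_mean,
                 size_fold_change = size_fold_change),
            class = "perturbation_config")
}

#' Apply a perturbation to a ground-truth panel
#'
#' @param truth a [panel_truth()] table (baseline).
#' @param pcfg a [perturbation_config()].
#' @param cfg the panel's [clone_panel_config()] (for the protein rates).
#' @return A new truth table with updated `k_on`, `T`, `b`, `f` and
#'   analytic moments, plus a logical column `size_modulated`.
#' @export
apply_perturbation <- function(truth, pcfg, cfg) {
  stopifnot(inherits(pcfg, "perturbation_config"),
            is.data.frame(truth),
            all(c("clone_id", "b", "f", "analytic_mean") %in% names(truth)))
  above <- truth$analytic_mean > pcfg$size_threshold_mean
  f_new <- truth$f * pcfg$freq_fold_change
  b_new <- ifelse(above, truth$b * pcfg$size_fold_change, truth$b)
  out <- panel_truth(b_new, f_new, cfg, clone_id = truth$clone_id)
  # keep k_off (hence the integration site's switching kinetics) fixed:
  # only k_on and T change under the perturbation
  out$k_off <- truth$k_off
  out$T <- b_new * truth$k_off
  out$k_on <- f_new * truth$d_m
  mom <- lapply(seq_len(nrow(out)), function(i)
    analytic_mrna_moments(telegraph_params(out$k_on[i], out$k_off[i],
                                           out$T[i], d_m = out$d_m[i])))
  out$analytic_mean <- vapply(mom, `[[`, numeric(1), "mean")
  out$analytic_fano <- vapply(mom, `[[`, numeric(1), "fano")
  out$size_modulated <- above
  out
}

#' Run a paired baseline/perturbation experiment
#'
#' Generates the baseline panel, perturbs its ground truth, regenerates the
#' same clones under the perturbed kinetics, and returns both conditions.
#'
#' @param cfg a [clone_panel_config()].
#' @param pcfg a [perturbation_config()].
#' @param flow simulate flow tables for both conditions (default FALSE;
#'   the perturbation analysis runs on mRNA counts).
#' @param conditions labels for the two conditions.
#' @param truth optional baseline ground-truth table (columns `clone_id`,
#'   `b`, `f`) for a designed rather than randomly drawn panel.
#' @return List with `counts` (both conditions row-bound), `flow` (or
#'   NULL), `truth_before`, `truth_after`.
#' @export
run_perturbation_experiment <- function(cfg, pcfg = perturbation_config(),
                                        flow = FALSE,
                                        conditions = c("baseline", "tnfa"),
                                        truth = NULL) {
  base <- generate_clone_panel(cfg, condition = conditions[1], flow = flow,
                               truth = truth)
  truth_after <- apply_perturbation(base$truth, pcfg, cfg)
  pert <- generate_clone_panel(cfg, condition = conditions[2],
                               truth = truth_after, flow = flow)
  list(counts = rbind(base$counts, pert$counts),
       flow = if (flow) rbind(base$flow, pert$flow) else NULL,
       truth_before = base$truth, truth_after = truth_after)
}
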