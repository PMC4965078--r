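# Shared fixture builders. All panels are generated in code; sizes are kept
# small where the property under test does not need sampling precision.

small_panel_cfg <- function(n_clones = 3, n_cells_fish = 60,
                            n_events_flow = 400, seed = 101, ...) {
  clone_panel_config(n_clones = n_clones, n_cells_fish = n_cells_fish,
                     n_events_flow = n_events_flow, seed = seed, ...)
}

# population_summary row built directly from mean/cv2 (for estimator and
# manifold tests that need exact analytic placements)
summary_row <- function(mean, cv2, clone_id = "c", condition = "baseline",
                        n = 1000) {
  out <- data.frame(clone_id = clone_id, condition = condition, n = n,
                    mean = mean, variance = cv2 * mean^2,
                    cv2 = cv2, fano = cv2 * mean,
                    stringsAsFactors = FALSE)
  class(out) <- c("population_summary", class(out))
  out
}

# estimates table lying exactly on given (mean, B) coordinates
estimates_at <- function(means, Bs, condition = "baseline") {
  sm <- do.call(rbind, lapply(seq_along(means), function(i)
    summary_row(means[i], Bs[i] / means[i],
                clone_id = sprintf("clone_%02d", i), condition = condition)))
  estimate_bursts(sm, source = "fish")
}
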