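#' Kinetic parameters of the two-state telegraph promoter model
#'
#' Container for the six rates of the random-telegraph model of gene
#' expression: the promoter toggles OFF->ON at `k_on` (the burst-frequency
#' parameter) and ON->OFF at `k_off`; while ON it transcribes mRNA at rate
#' `T`; each mRNA is translated at rate `L` and degraded at `d_m`; protein
#' is degraded at `d_p`. The mean number of transcripts made per ON period,
#' `T / k_off`, is the transcriptional burst size.
#'
#' Rates carry no absolute time unit; by convention they are expressed per
#' mean mRNA lifetime, i.e. `d_m = 1` (the data the model describes contain
#' only rate ratios).
#'
#' @param k_on promoter activation rate (OFF -> ON), per unit time.
#' @param k_off promoter inactivation rate (ON -> OFF), per unit time.
#' @param T transcription rate while the promoter is ON.
#' @param L translation rate per mRNA (0 disables the protein stage).
#' @param d_m mRNA degradation rate per molecule; must be positive whenever
#'   `T > 0` so a stationary distribution exists.
#' @param d_p protein degradation rate per molecule.
#' @return An object of class `telegraph_params` (a named list of the six
#'   rates).
#' @examples
#' p <- telegraph_params(k_on = 1, k_off = 50, T = 250, d_m = 1)
#' burst_size_true(p)  # T / k_off = 5
#' @export
telegraph_params <- function(k_on, k_off, T, L = 0, d_m = 1, d_p = 0) {
  rates <- c(k_on = k_on, k_off = k_off, T = T, L = L, d_m = d_m, d_p = d_p)
  if (any(!is.finite(rates)))
    stop("all telegraph rates must be finite numbers", call. = FALSE)
  if (any(rates < 0))
    stop("negative rate(s): ",
         paste(names(rates)[rates < 0], collapse = ", "), call. = FALSE)
  if (T > 0 && d_m <= 0)
    stop("d_m must be > 0 when T > 0 (stationarity requires mRNA decay)",
         call. = FALSE)
  structure(as.list(rates), class = "telegraph_params")
}

#' @export
print.telegraph_params <- function(x, ...) {
  cat("Two-state telegraph model parameters (rates per unit time):\n")
  cat(sprintf("  k_on = %g, k_off = %g, T = %g, L = %g, d_m = %g, d_p = %g\n",
              x$k_on, x$k_off, x$T, x$L, x$d_m, x$d_p))
  if (x$k_off > 0)
    cat(sprintf("  burst size T/k_off = %g\n", x$T / x$k_off))
  invisible(x)
}

#' True burst size of a parameter set
#'
#' The kinetic burst size `b = T / k_off`: mean transcripts per promoter
#' ON period. Defined only for `k_off > 0`.
#'
#' @param params a [telegraph_params()] object.
#' @return Numeric burst size.
#' @export
burst_size_true <- function(params) {
  stopifnot(inherits(params, "telegraph_params"))
  if (params$k_off <= 0)
    stop("burst size T/k_off is undefined for k_off = 0", call. = FALSE)
  params$T / params$k_off
}

#' Analytic protein noise of the telegraph model
#'
#' Closed-form squared coefficient of variation of protein copy number in
#' the bursting regime:
#' \deqn{CV^2 = C (1 + T/k_{off}) / \langle P \rangle, \quad
#'       C = L / (d_m + d_p).}
#' The hyperbolic dependence on the mean is what places a promoter on a
#' constant-burst-size manifold in CV²-versus-mean space: changing only the
#' burst frequency `k_on` moves the mean while `C (1 + T/k_off)` stays fixed.
#'
#' @param params a [telegraph_params()] object with `k_off > 0` and
#'   `d_m + d_p > 0`.
#' @param mean_protein positive mean protein abundance `<P>`.
#' @return The predicted protein CV².
#' @examples
#' p <- telegraph_params(k_on = 0.5, k_off = 10, T = 40, L = 10000,
#'                       d_m = 1, d_p = 1)
#' analytic_protein_cv2(p, mean_protein = 25000)  # = 1
#' @export
analytic_protein_cv2 <- function(params, mean_protein) {
  stopifnot(inherits(params, "telegraph_params"))
  if (!is.numeric(mean_protein) || length(mean_protein) != 1L ||
      mean_protein <= 0)
    stop("mean_protein must be a single positive number", call. = FALSE)
  if (params$k_off <= 0)
    stop("k_off must be > 0 (burst size T/k_off undefined)", call. = FALSE)
  if (params$d_m + params$d_p <= 0)
    stop("d_m + d_p must be > 0", call. = FALSE)
  C <- params$L / (params$d_m + params$d_p)
  C * (1 + params$T / params$k_off) / mean_protein
}

#' Stationary mRNA mean and Fano factor of the telegraph model
#'
#' Exact stationary moments of the mRNA copy-number distribution:
#' \deqn{\langle m \rangle = \frac{T k_{on}}{d_m (k_{on}+k_{off})}, \quad
#'   F = 1 + \frac{T k_{off}}{(k_{on}+k_{off}) (k_{on}+k_{off}+d_m)}.}
#' In the bursting limit (`k_off`, `T` large with `b = T/k_off` fixed and
#' `k_off >> k_on, d_m`) the Fano factor tends to `1 + b`, the classical
#' geometric-burst result; that limit is what makes the Fano factor an
#' operational burst-size estimate.
#'
#' @param params a [telegraph_params()] object with `d_m > 0`.
#' @return A list with elements `mean` and `fano`. For `T = 0` the mean is 0
#'   and `fano` is `NA` (noise of a degenerate distribution at zero).
#' @examples
#' analytic_mrna_moments(telegraph_params(k_on = 1, k_off = 50, T = 250))
#' @export
analytic_mrna_moments <- function(params) {
  stopifnot(inherits(params, "telegraph_params"))
  if (params$d_m <= 0)
    stop("d_m must be > 0 for stationary moments", call. = FALSE)
  ks <- params$k_on + params$k_off
  if (ks <= 0 && params$T > 0)
    stop("k_on + k_off must be > 0", call. = FALSE)
  if (params$T == 0)
    return(list(mean = 0, fano = NA_real_))
  m <- params$T * params$k_on / (params$d_m * ks)
  f <- 1 + params$T * params$k_off / (ks * (ks + params$d_m))
  list(mean = m, fano = f)
}

#' Serialize / deserialize telegraph parameters as JSON
#'
#' The JSON object uses exactly the keys `k_on`, `k_off`, `T`, `L`, `d_m`,
#' `d_p`, the interchange contract used by configuration files and the
#' ground-truth sidecar of the synthetic panel generator.
#'
#' @param params a [telegraph_params()] object.
#' @param txt a JSON string or a path to a JSON file.
#' @return `params_to_json()` returns a JSON string; `params_from_json()`
#'   returns a [telegraph_params()] object.
#' @export
params_to_json <- function(params) {
  stopifnot(inherits(params, "telegraph_params"))
  jsonlite::toJSON(params[c("k_on", "k_off", "T", "L", "d_m", "d_p")],
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt)
  need <- c("k_on", "k_off", "T", "L", "d_m", "d_p")
  missing <- setdiff(c("k_on", "k_off", "T"), names(x))
  if (length(missing))
    stop("JSON parameter block lacks key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  defaults <- list(L = 0, d_m = 1, d_p = 0)
  for (k in names(defaults)) if (is.null(x[[k]])) x[[k]] <- defaults[[k]]
  telegraph_params(k_on = x$k_on, k_off = x$k_off, T = x$T,
                   L = x$L, d_m = x$d_m, d_p = x$d_p)
}
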