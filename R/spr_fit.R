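# Steady-state surface plasmon resonance analysis: one-site binding
# isotherm, nonlinear least-squares fit with standard errors, and
# titration simulation for recovery testing.

#' One-site binding isotherm
#'
#' Equilibrium response `Req = Rmax * C / (KD + C)` relating analyte
#' concentration to the steady-state SPR response.
#'
#' @param concentration Analyte concentration, molar (0 allowed).
#' @param kd Dissociation constant, molar (> 0).
#' @param rmax Saturation response, RU (> 0).
#' @return Response in RU.
#' @export
#' @examples
#' isotherm(21e-6, kd = 21e-6, rmax = 100)  # half-saturation: 50 RU
isotherm <- function(concentration, kd, rmax) {
  if (any(concentration < 0) || kd <= 0 || rmax <= 0)
    stop("concentration must be >= 0 and kd, rmax > 0")
  rmax * concentration / (kd + concentration)
}

#' Simulate a steady-state titration series
#'
#' Responses are isotherm values under multiplicative Gaussian noise
#' (`* (1 + N(0, noise_cv))`), floored at zero; deterministic for a
#' fixed seed. The default concentration grid is two-fold dilutions
#' from 50 uM down to ~100 nM, the usual span of a weak-affinity SPR
#' dilution series.
#'
#' @param kd,rmax Ground-truth isotherm parameters (molar, RU).
#' @param concentrations Molar concentration grid; default two-fold
#'   dilutions 50 uM ... 0.098 uM.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   noise.
#' @param replicates Replicates per concentration (default 3).
#' @param seed RNG seed (optional).
#' @param analyte,ligand Labels carried into the series.
#' @return Data frame (`TitrationSeries`): `analyte`, `ligand`,
#'   `concentration` (M), `replicate`, `response` (RU).
#' @export
simulate_titration <- function(kd, rmax, concentrations = NULL,
                               noise_cv = 0.02, replicates = 3L,
                               seed = NULL, analyte = "analyte",
                               ligand = "ligand") {
  stopifnot(noise_cv >= 0, replicates >= 1L)
  if (is.null(concentrations))
    concentrations <- 50e-6 / 2^(0:9)
  if (!is.null(seed)) set.seed(seed)
  conc <- rep(concentrations, each = replicates)
  repl <- rep(seq_len(replicates), times = length(concentrations))
  mu <- isotherm(conc, kd, rmax)
  resp <- pmax(0, mu * (1 + stats::rnorm(length(mu), 0, noise_cv)))
  data.frame(analyte = analyte, ligand = ligand,
             concentration = conc, replicate = repl, response = resp,
             stringsAsFactors = FALSE)
}

#' Fit a one-site binding isotherm to a titration series
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt) of
#' `(KD, Rmax)`; standard errors come from the covariance of the
#' linearized problem at the optimum. The default start takes KD as the
#' concentration nearest half the maximum observed response and
#' `Rmax = 1.1 x` the maximum response. Non-convergence yields a result
#' with `converged = FALSE`, never an exception.
#'
#' @param series Titration data frame with `concentration` (M) and
#'   `response` (RU) columns, >= 4 distinct concentrations.
#' @param start Optional `c(kd, rmax)` start values.
#' @param weights `"none"` (default) or `"invvar"` for 1/variance
#'   weights across replicates per concentration.
#' @return A list (`affinity_fit`): `kd`, `rmax`, `kd_se`, `rmax_se`
#'   (molar/RU), `residual_rms` (RU), `converged`,
#'   `poorly_determined` (`kd_se/kd > 0.5`), `approximate` (KD beyond
#'   half the top concentration), `n`.
#' @export
fit_isotherm <- function(series, start = NULL,
                         weights = c("none", "invvar")) {
  weights <- match.arg(weights)
  stopifnot(all(c("concentration", "response") %in% names(series)))
  conc <- series$concentration
  resp <- series$response
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (length(unique(conc)) < 4L)
    stop("need at least 4 distinct concentrations to fit")
  if (all(resp == 0)) stop("all responses are zero; nothing to fit")
  if (is.null(start)) {
    half <- max(resp) / 2
    start <- c(kd = conc[which.min(abs(resp - half))],
               rmax = 1.1 * max(resp))
  } else {
    start <- c(kd = unname(start[1]), rmax = unname(start[2]))
  }
  w <- NULL
  if (weights == "invvar") {
    v <- stats::ave(resp, conc, FUN = stats::var)
    v[!is.finite(v) | v <= 0] <- min(v[v > 0 & is.finite(v)], 1)
    w <- 1 / v
  }
  dat <- data.frame(conc = conc, resp = resp)
  args <- list(resp ~ rmax * conc / (kd + conc), data = dat,
               start = as.list(start),
               lower = c(kd = 1e-12, rmax = 1e-9),
               control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(w)) args$weights <- w
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args),
                  error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(kd = NA_real_, rmax = NA_real_,
                          kd_se = NA_real_, rmax_se = NA_real_,
                          residual_rms = NA_real_, converged = FALSE,
                          poorly_determined = NA, approximate = NA,
                          n = nrow(series)),
                     class = "affinity_fit"))
  }
  co <- summary(fit)$coefficients
  kd <- co["kd", "Estimate"]; rmax <- co["rmax", "Estimate"]
  kd_se <- co["kd", "Std. Error"]; rmax_se <- co["rmax", "Std. Error"]
  structure(list(
    kd = kd, rmax = rmax, kd_se = kd_se, rmax_se = rmax_se,
    residual_rms = sqrt(mean(stats::residuals(fit)^2)),
    converged = isTRUE(fit$convInfo$isConv),
    poorly_determined = is.finite(kd_se) && kd_se / kd > 0.5,
    approximate = kd > 0.5 * max(conc),
    n = nrow(series)
  ), class = "affinity_fit")
}

#' @export
print.affinity_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<affinity_fit> not converged\n")
    return(invisible(x))
  }
  cat(sprintf("<affinity_fit> KD %.3g +/- %.2g M, Rmax %.4g +/- %.2g RU (n = %d)%s%s\n",
              x$kd, x$kd_se, x$rmax, x$rmax_se, x$n,
              if (isTRUE(x$poorly_determined)) " [poorly determined]" else "",
              if (isTRUE(x$approximate)) " [approximate: KD beyond titration range]" else ""))
  invisible(x)
}

#' Read/write titration series CSV
#'
#' Column layout: `concentration_M`, `replicate`, `response_RU`, with
#' optional `analyte` and `ligand` columns.
#'
#' @param path CSV file.
#' @return Titration data frame as accepted by [fit_isotherm()].
#' @export
read_titration_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("concentration_M", "replicate", "response_RU") %in% names(d)))
  data.frame(
    analyte = if ("analyte" %in% names(d)) d$analyte else "analyte",
    ligand = if ("ligand" %in% names(d)) d$ligand else "ligand",
    concentration = d$concentration_M, replicate = d$replicate,
    response = d$response_RU, stringsAsFactors = FALSE)
}

#' @rdname read_titration_csv
#' @param series Titration data frame.
#' @export
write_titration_csv <- function(series, path) {
  utils::write.csv(
    data.frame(analyte = series$analyte, ligand = series$ligand,
               concentration_M = series$concentration,
               replicate = series$replicate,
               response_RU = series$response),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
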