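# 1:1 (Langmuir) interaction model for AKAP-binding measurements:
# steady-state saturation fits of Response = Rmax * c / (KD + c) and local
# kinetic fits of biolayer-interferometry association / dissociation
# phases. Nonlinear least squares via minpack.lm; loss is unweighted.

#' Steady-state 1:1 saturation response
#'
#' @param conc Analyte concentration (molar).
#' @param Rmax Saturating response (instrument units).
#' @param KD Equilibrium dissociation constant (molar).
#' @return Response `Rmax * conc / (KD + conc)`.
#' @export
steady_state_response <- function(conc, Rmax, KD) Rmax * conc / (KD + conc)

.half_max_conc <- function(conc, response) {
  # interpolated concentration at half-maximal response
  half <- max(response) / 2
  o <- order(conc)
  conc <- conc[o]; response <- response[o]
  above <- which(response >= half)
  if (length(above) == 0 || above[1] == 1) return(stats::median(conc))
  i <- above[1]
  frac <- (half - response[i - 1]) / (response[i] - response[i - 1])
  conc[i - 1] + frac * (conc[i] - conc[i - 1])
}

#' Fit the steady-state 1:1 binding model to a titration
#'
#' Nonlinear least squares of the rectangular hyperbola
#' `Response = Rmax * c / (KD + c)`. Default initialisation uses the
#' maximal response for Rmax and the interpolated concentration at
#' half-maximal response for KD.
#'
#' @param conc Concentrations in molar (>= 3 distinct positive values).
#' @param response Measured responses (same length).
#' @param init Optional named list with starting values `Rmax`, `KD`.
#' @return A `binding_fit` list: `Rmax`, `KD` (molar), their standard
#'   errors (`se`), residual sum of squares `rss`, `n`, `model = "steady"`.
#' @export
steady_state_fit <- function(conc, response, init = NULL) {
  stopifnot(length(conc) == length(response))
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (length(unique(conc)) < 3) stop("need at least 3 distinct concentrations")
  if (all(response == 0)) stop("all responses are zero")
  if (is.null(init))
    init <- list(Rmax = max(response), KD = .half_max_conc(conc, response))
  dat <- data.frame(conc = conc, response = response)
  fit <- minpack.lm::nlsLM(response ~ Rmax * conc / (KD + conc),
                           data = dat, start = init,
                           lower = c(Rmax = 0, KD = .Machine$double.xmin),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!isTRUE(fit$convInfo$isConv))
    stop("steady-state fit did not converge")
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Rmax = NA_real_, KD = NA_real_))
  out <- list(Rmax = unname(est["Rmax"]), KD = unname(est["KD"]),
              kon = NA_real_, koff = NA_real_,
              se = c(Rmax = unname(se["Rmax"]), KD = unname(se["KD"])),
              rss = sum(stats::resid(fit)^2), n = length(conc),
              model = "steady")
  class(out) <- "binding_fit"
  out
}

#' Derive steady-state points from kinetic traces
#'
#' The equilibrium response of a trace is taken as the time-average of the
#' final fraction `frac` of its association phase.
#'
#' @param traces List of kinetic traces (see [kinetic_fit()]).
#' @param frac Final fraction of the association phase to average.
#' @return Data frame with columns `conc`, `response`.
#' @export
steady_state_from_traces <- function(traces, frac = 0.05) {
  do.call(rbind, lapply(traces, function(tr) {
    t <- tr$association$time
    keep <- t >= max(t) * (1 - frac)
    data.frame(conc = tr$concentration,
               response = mean(tr$association$response[keep]))
  }))
}

.fit_dissociation <- function(time, response) {
  if (length(time) < 5) stop("dissociation phase with fewer than 5 samples")
  r0 <- response[1]
  if (max(response) - min(response) < 1e-12 * max(abs(response), 1))
    return(list(R0 = r0, koff = 0, flat = TRUE))
  dat <- data.frame(t = time - time[1], r = response)
  fit <- minpack.lm::nlsLM(r ~ R0 * exp(-koff * t), data = dat,
                           start = list(R0 = r0, koff = 0.1 / max(dat$t[dat$t > 0])),
                           lower = c(R0 = 0, koff = 0))
  est <- stats::coef(fit)
  list(R0 = unname(est["R0"]), koff = unname(est["koff"]),
       flat = unname(est["koff"]) < .Machine$double.eps)
}

.fit_association <- function(time, response) {
  if (length(time) < 5) stop("association phase with fewer than 5 samples")
  dat <- data.frame(t = time, r = response)
  fit <- minpack.lm::nlsLM(r ~ Req * (1 - exp(-kobs * t)), data = dat,
                           start = list(Req = max(response),
                                        kobs = 1 / max(time)),
                           lower = c(Req = 0, kobs = 0))
  est <- stats::coef(fit)
  list(Req = unname(est["Req"]), kobs = unname(est["kobs"]))
}

#' Local 1:1 kinetic fits of association / dissociation traces
#'
#' Each trace is fit locally: the dissociation phase as
#' `R(t) = R0 * exp(-koff * t)` and the association phase as
#' `R(t) = Req * (1 - exp(-kobs * t))` with `kobs = kon * c + koff`.
#' Per-trace `kon = (kobs - koff) / c` estimates are averaged; `KD` is
#' reported as `koff / kon`. A flat dissociation phase yields `koff ~ 0`
#' and flags the reported KD as a lower bound.
#'
#' @param traces List of traces, each a list with `concentration` (molar),
#'   `association` and `dissociation` data frames (`time`, `response`;
#'   times strictly increasing within a phase).
#' @return A `binding_fit` with `kon` (1/M/s), `koff` (1/s), `KD` (molar),
#'   `Rmax`, per-trace estimates in `per_trace`, and `kd_lower_bound`.
#' @export
kinetic_fit <- function(traces) {
  if (length(traces) < 1) stop("need at least one trace")
  per <- lapply(traces, function(tr) {
    stopifnot(all(diff(tr$association$time) > 0),
              all(diff(tr$dissociation$time) > 0))
    dis <- .fit_dissociation(tr$dissociation$time, tr$dissociation$response)
    ass <- .fit_association(tr$association$time, tr$association$response)
    kon <- max(ass$kobs - dis$koff, 0) / tr$concentration
    data.frame(conc = tr$concentration, kobs = ass$kobs, Req = ass$Req,
               koff = dis$koff, kon = kon, flat = dis$flat)
  })
  per <- do.call(rbind, per)
  kon <- mean(per$kon)
  koff <- mean(per$koff)
  lower_bound <- all(per$flat)
  KD <- if (kon > 0) koff / kon else NA_real_
  rmax <- mean(per$Req * (KD + per$conc) / per$conc)
  out <- list(Rmax = rmax, KD = KD, kon = kon, koff = koff,
              se = c(kon = stats::sd(per$kon) / sqrt(nrow(per)),
                     koff = stats::sd(per$koff) / sqrt(nrow(per))),
              rss = NA_real_, n = nrow(per), model = "kinetic",
              per_trace = per, kd_lower_bound = lower_bound)
  class(out) <- "binding_fit"
  out
}

#' Read a titration or trace CSV
#'
#' Steady-state files need columns `concentration`, `response`; kinetic
#' files additionally `time` and `phase` (`association`/`dissociation`).
#' Concentrations are in molar unless a `conc_unit` argument
#' (`"M"`, `"uM"`, `"nM"`) says otherwise.
#'
#' @param path CSV path.
#' @param conc_unit Concentration unit tag of the file.
#' @return A data frame with `concentration` converted to molar.
#' @export
read_binding_csv <- function(path, conc_unit = c("M", "uM", "nM")) {
  conc_unit <- match.arg(conc_unit)
  if (!file.exists(path)) stop("CSV file not found: ", path)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("concentration", "response")
  if (!all(need %in% names(dat)))
    stop("CSV must contain columns: ", paste(need, collapse = ", "),
         " (line 1)")
  dat$concentration <- suppressWarnings(as.numeric(dat$concentration))
  dat$response <- suppressWarnings(as.numeric(dat$response))
  if (any(!is.finite(dat$concentration)) || any(!is.finite(dat$response))) {
    bad <- which(!is.finite(dat$concentration) | !is.finite(dat$response))[1]
    stop("malformed CSV value at line ", bad + 1L)
  }
  scale <- c(M = 1, uM = 1e-6, nM = 1e-9)[[conc_unit]]
  dat$concentration <- dat$concentration * scale
  dat
}

#' Fitted binding parameters as a plain list for JSON export
#'
#' @param fit A `binding_fit`.
#' @return Plain list of numeric fields.
#' @export
binding_fit_report <- function(fit) {
  list(model = fit$model, Rmax = fit$Rmax, KD_molar = fit$KD,
       kon = fit$kon, koff = fit$koff, se = as.list(fit$se),
       rss = fit$rss, n = fit$n)
}
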