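# Data reduction for the wet-lab validation assays: percentage inhibition of
# TNF-alpha mediated cytotoxicity (CCK8 optical densities) and equilibrium
# dissociation constants from steady-state SPR responses.

#' Percentage inhibition of TNF-alpha mediated cytotoxicity
#'
#' Normalizes the optical density (OD 450 nm) rescue in an actinomycin D /
#' TNF-alpha cytotoxicity assay:
#' \deqn{100 \times (OD_{actD+TNF+compound} - OD_{actD+TNF}) /
#'       (OD_{actD} - OD_{actD+TNF})}
#' so 0 corresponds to the TNF-alpha-only control and 100 to the
#' no-TNF-alpha control. The result is not clamped: values below 0 or above
#' 100 are reported as computed. Adding a constant to all three ODs leaves
#' the result unchanged.
#'
#' @param od_component OD with actinomycin D + TNF-alpha + compound.
#' @param od_tnf OD with actinomycin D + TNF-alpha (cytotoxicity control).
#' @param od_actd OD with actinomycin D only (viability control).
#' @return Percentage inhibition (vectorized over `od_component`).
#' @examples
#' percent_inhibition(od_component = 0.9, od_tnf = 0.4, od_actd = 1.4)
#' @export
percent_inhibition <- function(od_component, od_tnf, od_actd) {
  stopifnot(
    is.numeric(od_component), is.numeric(od_tnf), is.numeric(od_actd),
    all(od_component >= 0), all(od_tnf >= 0), all(od_actd >= 0)
  )
  if (any(od_actd == od_tnf)) {
    abort("Degenerate controls: od_actd equals od_tnf, the denominator is zero.")
  }
  (od_component - od_tnf) / (od_actd - od_tnf) * 100
}

#' Steady-state response of the 1:1 binding model
#'
#' \eqn{R(C) = R_{max} C / (K_D + C)}: the Langmuir isotherm relating analyte
#' concentration to equilibrium SPR response. At `C = kd` the response is
#' half-maximal.
#'
#' @param concentration Analyte concentrations (same units as `kd`).
#' @param kd Equilibrium dissociation constant (> 0).
#' @param rmax Maximal response (> 0).
#' @return Model responses.
#' @export
binding_response <- function(concentration, kd, rmax) {
  stopifnot(kd > 0, rmax > 0, all(concentration >= 0))
  rmax * concentration / (kd + concentration)
}

#' Two-fold serial dilution series
#'
#' Convenience constructor for the concentration designs used in SPR runs,
#' e.g. `dilution_series(6.25, 400)` gives the 8-point 6.25-400 series.
#'
#' @param from Lowest concentration.
#' @param to Highest concentration (must be `from` times a power of `fold`).
#' @param fold Dilution factor (default 2).
#' @return Numeric vector of concentrations, ascending.
#' @export
dilution_series <- function(from, to, fold = 2) {
  stopifnot(from > 0, to >= from, fold > 1)
  n <- round(log(to / from, fold))
  from * fold^(0:n)
}

#' Fit the steady-state 1:1 binding model
#'
#' Least-squares fit of \eqn{R(C) = R_{max} C / (K_D + C)} to
#' concentration-response pairs, as used to reduce equilibrium SPR
#' responses to a dissociation constant. Starting values are
#' \eqn{R_{max,0} = \max R} and \eqn{K_{D,0}} the concentration whose
#' response is nearest half-maximal, which is robust for 2-fold dilution
#' designs; Levenberg-Marquardt iteration then refines both parameters to a
#' relative tolerance of 1e-8. Replicate points are fitted individually
#' unless `average = TRUE` pre-averages per concentration.
#'
#' @param concentrations Analyte concentrations (at least 3 distinct
#'   positive values).
#' @param responses Equilibrium responses (non-negative, same length).
#' @param average Average replicate responses per concentration before
#'   fitting (default `FALSE`).
#' @return A `binding_fit` object with elements `kd`, `rmax`,
#'   `residual_sse`, `n_points`, and the fitted data; methods: [tidy()],
#'   [glance()], [autoplot()].
#' @examples
#' conc <- dilution_series(6.25, 400)
#' resp <- binding_response(conc, kd = 35, rmax = 100)
#' fit_kd(conc, resp)
#' @export
fit_kd <- function(concentrations, responses, average = FALSE) {
  stopifnot(
    is.numeric(concentrations), is.numeric(responses),
    length(concentrations) == length(responses)
  )
  if (anyNA(concentrations) || anyNA(responses)) abort("Missing values in binding data.")
  if (any(responses < 0)) abort("Responses must be non-negative.")
  if (any(concentrations <= 0)) abort("Concentrations must be positive.")
  dat <- tibble(concentration = concentrations, response = responses)
  if (average) {
    dat <- dat |> summarise(response = mean(response), .by = concentration)
  }
  if (n_distinct(dat$concentration) < 3) {
    abort("Underdetermined fit: at least 3 distinct concentrations are required.")
  }
  if (all(dat$response == 0)) {
    abort("All responses are zero: kd is unidentifiable (rmax at the 0 boundary).")
  }

  # starting values: Hanes-Woolf linearization C/R = C/rmax + kd/rmax when
  # it yields admissible parameters, otherwise max-response / nearest
  # half-max heuristics (robust for 2-fold dilution designs)
  rmax0 <- max(dat$response)
  kd0 <- dat$concentration[which.min(abs(dat$response - rmax0 / 2))][1]
  pos <- dat$response > 0
  if (sum(pos) >= 3) {
    hw <- stats::lm(I(concentration / response) ~ concentration, data = dat[pos, ])
    slope <- stats::coef(hw)[[2]]
    intercept <- stats::coef(hw)[[1]]
    if (is.finite(slope) && slope > 0 && is.finite(intercept) && intercept > 0) {
      rmax0 <- 1 / slope
      kd0 <- intercept / slope
    }
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ rmax * concentration / (kd + concentration),
      data = dat,
      start = list(rmax = rmax0, kd = kd0),
      lower = c(rmax = 0, kd = .Machine$double.eps),
      control = minpack.lm::nls.lm.control(
        ftol = 1e-15, ptol = 1e-15, maxiter = 500
      )
    ),
    error = function(e) {
      abort(paste0(
        "1:1 binding fit failed to converge (last start rmax=", signif(rmax0, 6),
        ", kd=", signif(kd0, 6), "): ", conditionMessage(e)
      ))
    }
  )
  est <- stats::coef(fit)
  if (!is.finite(est[["kd"]]) || est[["kd"]] <= 0 || est[["rmax"]] <= 0) {
    abort("1:1 binding fit returned a non-positive kd or rmax.")
  }
  structure(
    list(
      kd = unname(est[["kd"]]),
      rmax = unname(est[["rmax"]]),
      residual_sse = sum(stats::resid(fit)^2),
      n_points = nrow(dat),
      data = dat,
      fit = fit
    ),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(
    "<binding_fit> 1:1 steady-state model\n",
    "  KD   = ", signif(x$kd, 6), "\n",
    "  Rmax = ", signif(x$rmax, 6), "\n",
    "  SSE  = ", signif(x$residual_sse, 6), " over ", x$n_points, " points\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn fit_kd Parameter estimates in broom layout (`term`,
#'   `estimate`, `std.error`).
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @export
tidy.binding_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"])
  )
}

#' @describeIn fit_kd One-row fit summary (`kd`, `rmax`, `residual_sse`,
#'   `n_points`).
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(
    kd = x$kd, rmax = x$rmax,
    residual_sse = x$residual_sse, n_points = x$n_points
  )
}

#' @describeIn fit_kd Concentration-response plot with the fitted isotherm
#'   (log-scaled concentration axis).
#' @param object A `binding_fit`.
#' @export
autoplot.binding_fit <- function(object, ...) {
  grid <- tibble(
    concentration = exp(seq(
      log(min(object$data$concentration)),
      log(max(object$data$concentration)),
      length.out = 200
    ))
  ) |>
    mutate(response = binding_response(concentration, object$kd, object$rmax))
  ggplot2::ggplot(object$data, ggplot2::aes(concentration, response)) +
    ggplot2::geom_line(data = grid, color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Concentration", y = "Response",
      title = sprintf("1:1 steady-state fit: KD = %.3g, Rmax = %.3g", object$kd, object$rmax)
    )
}
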