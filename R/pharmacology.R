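#' Four-parameter Hill dose-response parameters
#'
#' @param y0 response with vehicle, % MPA.
#' @param ymax maximal response, % MPA (`ymax >= y0`).
#' @param h Hill slope (> 0).
#' @param ec50 dose at half-maximal response, mg/kg (> 0).
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(y0, ymax, h, ec50) {
  if (ec50 <= 0) stop("ec50 must be > 0")
  if (h <= 0) stop("Hill slope must be > 0")
  if (ymax < y0) stop("ymax must be >= y0")
  structure(list(y0 = y0, ymax = ymax, h = h, ec50 = ec50),
            class = "hill_params")
}

#' High-dose collapse parameters
#'
#' Inverse sigmoid multiplying the Hill curve:
#' `collapse_factor(d) = c50^h_col / (d^h_col + c50^h_col)`, equal to 1 at
#' zero dose and 1/2 at `c50`.
#'
#' @param c50 dose halving the drug effect, mg/kg.
#' @param h_col collapse slope.
#' @return An object of class `collapse_params`.
#' @export
collapse_params <- function(c50, h_col = 1) {
  if (c50 <= 0 || h_col <= 0) stop("c50 and h_col must be > 0")
  structure(list(c50 = c50, h_col = h_col), class = "collapse_params")
}

#' Evaluate a Hill curve, optionally with a high-dose collapse
#'
#' @param dose dose vector (>= 0).
#' @param params a [hill_params()] object.
#' @param collapse optional [collapse_params()]; when given, the
#'   drug-dependent part of the response is multiplied by the collapse
#'   factor.
#' @return Response in % MPA.
#' @export
hill_response <- function(dose, params, collapse = NULL) {
  if (any(dose < 0)) stop("doses must be >= 0")
  frac <- ifelse(dose == 0, 0,
                 dose^params$h / (dose^params$h + params$ec50^params$h))
  y <- params$y0 + (params$ymax - params$y0) * frac
  if (!is.null(collapse)) {
    cf <- collapse_factor(dose, collapse)
    y <- params$y0 + (y - params$y0) * cf
  }
  y
}

#' @rdname hill_response
#' @export
collapse_factor <- function(dose, collapse) {
  collapse$c50^collapse$h_col / (dose^collapse$h_col + collapse$c50^collapse$h_col)
}

#' Maximum possible analgesia (MPA) from withdrawal thresholds
#'
#' \deqn{\%MPA(t) = 100 \frac{WD_{50}(t) - WD_{50}(predrug)}
#'                        {WD_{50}(prePNI) - WD_{50}(predrug)}.}
#' Values may leave `[0, 100]` (negative MPA means drug-worsened
#' allodynia) and are reported unclipped; set `clip = TRUE` for the
#' clipped view used in plots.
#'
#' @param wd50 withdrawal threshold(s) at the measured timepoint(s), g.
#' @param wd50_predrug post-injury, pre-drug threshold, g.
#' @param wd50_prepni pre-injury baseline threshold, g.
#' @param clip clip to `[0, 100]`?
#' @return MPA in percent.
#' @export
compute_mpa <- function(wd50, wd50_predrug, wd50_prepni, clip = FALSE) {
  den <- wd50_prepni - wd50_predrug
  if (abs(den) < 1e-12) stop("prePNI and predrug thresholds are equal")
  mpa <- 100 * (wd50 - wd50_predrug) / den
  if (clip) mpa <- pmin(pmax(mpa, 0), 100)
  mpa
}

#' Inverse of the MPA transform (threshold from MPA)
#'
#' @inheritParams compute_mpa
#' @param mpa percent MPA.
#' @return Withdrawal threshold, g.
#' @export
wd50_from_mpa <- function(mpa, wd50_predrug, wd50_prepni) {
  wd50_predrug + mpa / 100 * (wd50_prepni - wd50_predrug)
}

#' Reduce a repeated-measures withdrawal table to one MPA per animal
#'
#' Behavioral testing follows each injection with several hourly
#' measurements; dose-response fitting needs one response per animal.
#' `"max_4h"` takes each animal's maximum MPA over the observation
#' window (the conventional "maximum possible analgesia over four
#' hours"); `"peak_time"` takes every animal's MPA at the single
#' timepoint where the group-mean response peaks; `"raw"` returns all
#' measurements unreduced.
#'
#' @param table data.frame with columns `animal_id`, `dose_mgkg`,
#'   `time_h`, `mpa` (as emitted by [gen_behavioral()]).
#' @param mode reduction mode.
#' @return data.frame with `animal_id`, `dose_mgkg`, `mpa`.
#' @export
mpa_by_animal <- function(table, mode = c("max_4h", "peak_time", "raw")) {
  mode <- match.arg(mode)
  if (mode == "raw")
    return(table[, c("animal_id", "dose_mgkg", "mpa")])
  if (mode == "peak_time") {
    by_time <- stats::aggregate(mpa ~ time_h, table, mean)
    t_peak <- by_time$time_h[which.max(by_time$mpa)]
    sub <- table[table$time_h == t_peak, ]
    return(sub[, c("animal_id", "dose_mgkg", "mpa")])
  }
  stats::aggregate(mpa ~ animal_id + dose_mgkg, table, max)
}

#' Fit a four-parameter Hill curve to dose-response data
#'
#' Nonlinear least squares with Levenberg-Marquardt. Starting values:
#' `y0` = minimum response, `ymax` = maximum, `ec50` = median dose on the
#' log scale, `h` = 1; the slope is bounded to (0.1, 10]. Specific doses
#' (e.g. a high dose suspected of a collapse) can be excluded.
#'
#' @param doses,responses paired vectors (per-animal values or means).
#' @param exclude doses to drop before fitting.
#' @param fix optional named list fixing parameters (e.g.
#'   `list(ymax = 31.2)`).
#' @return list with `params` ([hill_params()]), `fit` (the nls object),
#'   `residual_sd` and the data used.
#' @export
fit_hill <- function(doses, responses, exclude = NULL, fix = list()) {
  keep <- !(doses %in% exclude)
  d <- doses[keep]; y <- responses[keep]
  if (length(unique(d)) < 4) stop("need at least 4 distinct doses after exclusion")
  pos <- unique(d[d > 0])
  start <- list(y0 = min(y), ymax = max(y),
                h = 1, lec50 = stats::median(log(pos)))
  lower <- c(-Inf, -Inf, 0.1, log(min(pos)) - 8)
  upper <- c(Inf, Inf, 10, log(max(pos)) + 8)
  for (nm in names(fix)) {
    start[[nm]] <- NULL
  }
  keep_par <- c("y0", "ymax", "h", "lec50") %in% names(start)
  dat <- c(list(d = d, y = y), fix)
  model <- y ~ y0 + (ymax - y0) * ifelse(d == 0, 0,
            d^h / (d^h + exp(lec50)^h))
  fit <- tryCatch(
    minpack.lm::nlsLM(model, start = start,
                      lower = lower[keep_par], upper = upper[keep_par],
                      data = dat,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Hill fit failed (starting values: ",
                             paste(names(start), signif(unlist(start), 3),
                                   sep = "=", collapse = ", "), "): ",
                             conditionMessage(e)))
  co <- as.list(c(stats::coef(fit), unlist(fix)))
  params <- hill_params(co$y0, co$ymax, co$h, exp(co$lec50))
  list(params = params, fit = fit,
       residual_sd = stats::sigma(fit),
       data = data.frame(dose = d, response = y))
}

#' Fit the Hill-times-collapse product model
#'
#' Fits \eqn{Y_{col}(d) = Y_0 + (Y(d) - Y_0) \cdot
#'   \frac{C_{50}^{H_{col}}}{d^{H_{col}} + C_{50}^{H_{col}}}} by least
#' squares, with the Hill amplitude `ymax` fixed to a value obtained from
#' an independent (non-collapsing) estimate, as the collapse and the
#' amplitude are not jointly identifiable on a single declining arm.
#'
#' @param doses,responses paired data including the declining high-dose arm.
#' @param fixed_ymax amplitude of the underlying Hill curve (required).
#' @param y0 optional fixed baseline; fitted if `NULL`.
#' @return list with `hill` ([hill_params()]), `collapse`
#'   ([collapse_params()]), `fit`, `residual_sd`, and `identifiable`
#'   (FALSE when no high-dose decline is present, flagged not silent).
#' @export
fit_hill_collapse <- function(doses, responses, fixed_ymax, y0 = NULL) {
  if (missing(fixed_ymax)) stop("fixed_ymax is required")
  d <- doses; y <- responses
  if (length(unique(d)) < 5) stop("need at least 5 distinct doses")
  # crude decline check: mean response at top dose below the curve maximum
  ag <- stats::aggregate(y, list(dose = d), mean)
  identifiable <- ag$x[which.max(ag$dose)] < max(ag$x) - 1e-9
  if (!identifiable)
    warning("no high-dose decline present; collapse parameters weakly identified")
  fit_y0 <- is.null(y0)
  pos <- unique(d[d > 0])
  start <- list(h = 1, lec50 = stats::median(log(pos)),
                lc50 = log(max(pos)), h_col = 2)
  if (fit_y0) start <- c(list(y0 = min(y)), start)
  model <- if (fit_y0)
    y ~ y0 + (fixed_ymax - y0) * ifelse(d == 0, 0, d^h / (d^h + exp(lec50)^h)) *
      (exp(lc50)^h_col / (d^h_col + exp(lc50)^h_col))
  else
    y ~ y0_fixed + (fixed_ymax - y0_fixed) *
      ifelse(d == 0, 0, d^h / (d^h + exp(lec50)^h)) *
      (exp(lc50)^h_col / (d^h_col + exp(lc50)^h_col))
  dat <- list(fixed_ymax = fixed_ymax, d = d, y = y)
  if (!fit_y0) dat$y0_fixed <- y0
  lower <- c(if (fit_y0) -Inf, 0.1, log(min(pos)) - 8, log(min(pos)) - 4, 0.1)
  upper <- c(if (fit_y0) Inf, 10, log(max(pos)) + 8, log(max(pos)) + 6, 10)
  fit <- minpack.lm::nlsLM(model, start = start, data = dat,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  co <- as.list(stats::coef(fit))
  y0_out <- if (fit_y0) co$y0 else y0
  list(hill = hill_params(y0_out, fixed_ymax, co$h, exp(co$lec50)),
       collapse = collapse_params(exp(co$lc50), co$h_col),
       fit = fit, residual_sd = stats::sigma(fit),
       identifiable = identifiable)
}

#' Loewe dose equivalence: dose of drug a matching a dose of drug b
#'
#' Closed form obtained by equating the two Hill responses (shared `y0`,
#' with \eqn{Y^a_{max} \ge Y^b_{max}}):
#' \deqn{a_{eq}(b) = \left[\frac{(EC^a_{50})^{H_a} (Y^b_{max}-Y_0) b^{H_b}}
#'  {(Y^a_{max}-Y_0)(EC^b_{50})^{H_b} - (Y^b_{max}-Y_0) b^{H_b}
#'   + (Y^a_{max}-Y_0) b^{H_b}}\right]^{1/H_a}.}
#'
#' @param b_dose dose of drug b (>= 0).
#' @param params_a,params_b [hill_params()] of the reference drug a and of
#'   drug b; `y0` must agree.
#' @return Equivalent dose of drug a.
#' @export
dose_equivalent <- function(b_dose, params_a, params_b) {
  if (params_a$ymax < params_b$ymax)
    stop("reference drug must have ymax_a >= ymax_b")
  if (abs(params_a$y0 - params_b$y0) > 1e-9)
    stop("dose equivalence assumes a shared y0")
  ea <- params_a$ymax - params_a$y0
  eb <- params_b$ymax - params_b$y0
  bh <- b_dose^params_b$h
  num <- params_a$ec50^params_a$h * eb * bh
  den <- ea * params_b$ec50^params_b$h - eb * bh + ea * bh
  if (any(den <= 0)) stop("drug b effect exceeds the range of drug a")
  ifelse(b_dose == 0, 0, (num / den)^(1 / params_a$h))
}

#' Additive (Loewe) response to a two-drug combination
#'
#' The dose of drug b is transposed to its drug-a equivalent and the sum
#' is evaluated on drug a's dose-response curve:
#' `Y_2drugs(a, b) = Y_a(a + a_eq(b))`.
#'
#' @param a_dose,b_dose doses of the two drugs.
#' @inheritParams dose_equivalent
#' @return Expected additive response, % MPA.
#' @export
additive_response <- function(a_dose, b_dose, params_a, params_b) {
  hill_response(a_dose + dose_equivalent(b_dose, params_a, params_b), params_a)
}

#' Classify an observed combination effect against Loewe additivity
#'
#' @param observed observed combination effect, % MPA.
#' @param expected additive expectation from [additive_response()].
#' @param uncertainty half-width of the acceptance band (e.g. the standard
#'   error of the observed mean).
#' @return `"synergistic"`, `"additive"` or `"antagonistic"`.
#' @export
classify_interaction <- function(observed, expected, uncertainty = 0) {
  if (uncertainty < 0) stop("uncertainty must be >= 0")
  if (observed > expected + uncertainty) "synergistic"
  else if (observed < expected - uncertainty) "antagonistic"
  else "additive"
}

#' Isobole of additive half-maximal combinations and the A50
#'
#' The isobole is the set of combinations (a, b) satisfying
#' `a + a_eq(b) = EC50_a`, i.e. producing the additive effect
#' `(Y0 + Ymax_a)/2`. Its endpoints are `(EC50_a, 0)` and `(0, b_eq)` with
#' `a_eq(b_eq) = EC50_a`. The theoretical A50 is the intersection of the
#' isobole with the fixed-dose-ratio ray `b = ratio * a`; the observed
#' A50, when a combination dose-response fit is supplied, is the point on
#' the ray whose fitted effect equals the same reference effect.
#'
#' @param params_a,params_b [hill_params()] for the two drugs.
#' @param ratio_b_over_a fixed dose ratio of the combination ray.
#' @param n number of isobole points.
#' @param observed_fit optional [hill_params()] fitted to the combination
#'   dose-response expressed in drug-a dose units along the ray.
#' @return list of class `isobole_result` with `curve` (data.frame a, b),
#'   `a50_theoretical` (named c(a, b)), and `a50_observed` or `NULL`.
#' @export
isobole_a50 <- function(params_a, params_b, ratio_b_over_a = 55,
                        n = 101, observed_fit = NULL) {
  if (ratio_b_over_a <= 0) stop("dose ratio must be > 0")
  ec <- params_a$ec50
  a_grid <- seq(0, ec, length.out = n)
  b_for_a <- function(a) {
    target <- ec - a
    if (target <= 0) return(0)
    if (dose_equivalent(1e9, params_a, params_b) < target) return(NA_real_)
    stats::uniroot(function(b) dose_equivalent(b, params_a, params_b) - target,
                   c(0, 1e9), tol = 1e-10)$root
  }
  curve <- data.frame(a = a_grid, b = vapply(a_grid, b_for_a, numeric(1)))
  # ray intersection: a + a_eq(ratio * a) = EC50_a
  f_ray <- function(a) a + dose_equivalent(ratio_b_over_a * a, params_a, params_b) - ec
  if (f_ray(ec) < 0)
    stop("fixed-ratio ray does not reach the isobole within the dose domain")
  a50a <- stats::uniroot(f_ray, c(0, ec), tol = 1e-10)$root
  a50_theoretical <- c(a = a50a, b = ratio_b_over_a * a50a)
  a50_observed <- NULL
  if (!is.null(observed_fit)) {
    target <- (params_a$y0 + params_a$ymax) / 2
    if (observed_fit$ymax > target) {
      aobs <- stats::uniroot(function(a) hill_response(a, observed_fit) - target,
                             c(1e-12, 1e9), tol = 1e-10)$root
      a50_observed <- c(a = aobs, b = ratio_b_over_a * aobs)
    }
  }
  structure(list(curve = curve, a50_theoretical = a50_theoretical,
                 a50_observed = a50_observed,
                 ratio_b_over_a = ratio_b_over_a),
            class = "isobole_result")
}

#' Semi-quantitative cold-response E-score
#'
#' Five successive evoked responses are each rated 0 (brief transient
#' response), 1 (response persisting under 5 s) or 2 (protracted repeated
#' response); the E-score is their sum, 0-10.
#'
#' @param ratings integer vector of exactly five ratings in `{0, 1, 2}`.
#' @return list of class `escore` with `ratings` and `total`.
#' @export
escore <- function(ratings) {
  if (length(ratings) != 5) stop("exactly five ratings required")
  if (!all(ratings %in% 0:2)) stop("ratings must be in {0, 1, 2}")
  structure(list(ratings = as.integer(ratings), total = sum(ratings)),
            class = "escore")
}
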