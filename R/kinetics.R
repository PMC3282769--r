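#' Fit a saturation dataset to a rectangular hyperbola
#'
#' Nonlinear least-squares fit of the Michaelis-Menten model
#' `v = Vmax * S / (Km + S)` to substrate concentration-activity data
#' (concentrations in mM, rates in U/mg, where one unit is 1 umol product
#' per minute).  Starting values are `Vmax0 = 1.2 * max(rate)` and
#' `Km0 =` the concentration whose rate is nearest `Vmax0 / 2`, making the
#' fit deterministic.  Standard errors come from the covariance of the
#' linearized problem at the optimum.
#'
#' @param concentrations Substrate concentrations (mM, > 0, distinct).
#' @param rates Observed rates (U/mg, >= 0).
#' @param substrate Optional substrate name, carried into the result.
#' @return A `hyperbolic_fit`: `vmax`, `km`, `se_vmax`, `se_km`,
#'   `efficiency` (= vmax/km, U mg^-1 mM^-1), `rss`, `substrate`, `fit`
#'   (the underlying `nls` object).
#' @export
fit_hyperbola <- function(concentrations, rates, substrate = "") {
  s <- as.numeric(concentrations); v <- as.numeric(rates)
  if (length(s) != length(v)) stop("concentrations and rates differ in ",
                                   "length", call. = FALSE)
  if (length(s) < 3L) stop("need at least 3 points to fit", call. = FALSE)
  if (any(s <= 0)) stop("concentrations must be strictly positive",
                        call. = FALSE)
  if (anyDuplicated(s)) stop("concentrations must be distinct", call. = FALSE)
  if (any(v < 0)) stop("rates must be non-negative", call. = FALSE)
  if (all(v == 0)) stop("degenerate data: all rates are zero", call. = FALSE)
  vmax0 <- 1.2 * max(v)
  km0 <- s[which.min(abs(v - vmax0 / 2))]
  df <- data.frame(s = s, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * s / (km + s), data = df,
                      start = list(vmax = vmax0, km = km0),
                      lower = c(vmax = 1e-12, km = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("hyperbolic fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))),
                 error = function(e) c(vmax = NA_real_, km = NA_real_))
  structure(
    list(vmax = unname(cf["vmax"]), km = unname(cf["km"]),
         se_vmax = unname(se["vmax"]), se_km = unname(se["km"]),
         efficiency = unname(cf["vmax"] / cf["km"]),
         rss = sum(residuals(fit)^2), substrate = substrate, fit = fit),
    class = "hyperbolic_fit")
}

#' @export
print.hyperbolic_fit <- function(x, ...) {
  cat("<hyperbolic_fit>", if (nzchar(x$substrate)) x$substrate, "\n")
  cat(sprintf("  Vmax = %.4g +/- %.2g U/mg\n", x$vmax, x$se_vmax))
  cat(sprintf("  Km   = %.4g +/- %.2g mM\n", x$km, x$se_km))
  cat(sprintf("  Vmax/Km = %.4g U mg^-1 mM^-1\n", x$efficiency))
  invisible(x)
}

#' Catalytic efficiency Vmax/Km
#'
#' @param fit A `hyperbolic_fit`, or a numeric Vmax (with `km` given).
#' @param km Km, when `fit` is a numeric Vmax.
#' @param signif_digits Optional rounding to significant digits, matching
#'   how efficiencies are conventionally reported (e.g. 3 s.f. gives 577
#'   for Vmax 813 / Km 1.41).
#' @return Efficiency in U mg^-1 mM^-1.
#' @export
catalytic_efficiency <- function(fit, km = NULL, signif_digits = NULL) {
  if (inherits(fit, "hyperbolic_fit")) {
    vmax <- fit$vmax; km <- fit$km
  } else {
    vmax <- as.numeric(fit)
    if (is.null(km)) stop("km required when fit is numeric", call. = FALSE)
  }
  if (km == 0) stop("km is zero; efficiency undefined", call. = FALSE)
  eff <- vmax / km
  if (!is.null(signif_digits)) eff <- signif(eff, signif_digits)
  eff
}

#' Fit an inhibition curve (logistic with Hill slope)
#'
#' Least-squares fit of `percent = 100 / (1 + ([I]/IC50)^h)` to
#' residual-activity data expressed as percent of the uninhibited rate,
#' as used for bisubstrate-analog inhibitors such as PAPU.
#'
#' @param concentrations Inhibitor concentrations (same units as assay);
#'   must include a zero-inhibitor reference.
#' @param percent_activity Percent of uninhibited activity, in \[0, 120\].
#' @param fix_hill Fix the Hill slope at 1 instead of fitting it?
#' @return List: `ic50`, `hill`, `rss`, `fit`.
#' @export
fit_inhibition <- function(concentrations, percent_activity,
                           fix_hill = FALSE) {
  i <- as.numeric(concentrations); p <- as.numeric(percent_activity)
  if (length(i) != length(p) || length(i) < 4L)
    stop("need at least 4 paired points", call. = FALSE)
  if (!any(i == 0)) stop("a zero-inhibitor reference point is required",
                         call. = FALSE)
  if (any(p < 0 | p > 120)) stop("percent activity must lie in [0, 120]",
                                 call. = FALSE)
  pos <- i > 0
  if (sum(pos) >= 2) {
    trend <- stats::coef(stats::lm(p[pos] ~ log(i[pos])))[2]
    if (!is.finite(trend) || trend >= 0)
      stop("no inhibition detected: activity does not decline with ",
           "inhibitor concentration", call. = FALSE)
  }
  ic50_0 <- i[pos][which.min(abs(p[pos] - 50))]
  df <- data.frame(i = i, p = p)
  if (fix_hill) {
    fit <- minpack.lm::nlsLM(p ~ 100 / (1 + (i / ic50)), data = df,
                             start = list(ic50 = ic50_0),
                             lower = c(ic50 = 1e-12))
    cf <- c(coef(fit), h = 1)
  } else {
    fit <- minpack.lm::nlsLM(p ~ 100 / (1 + (i / ic50)^h), data = df,
                             start = list(ic50 = ic50_0, h = 1),
                             lower = c(ic50 = 1e-12, h = 0.05))
    cf <- coef(fit)
  }
  list(ic50 = unname(cf["ic50"]), hill = unname(cf["h"]),
       rss = sum(residuals(fit)^2), fit = fit)
}

#' Equilibrium conversion of the limiting substrate for A + B <-> C + D
#'
#' For a transcarbamylation-type reaction with equilibrium constant
#' `Keq = [C][D] / ([A][B])` and initial substrate concentrations `a0`,
#' `b0` (no products initially), solves the unique physical root of
#' `x^2 = Keq (a0 - x)(b0 - x)` with `0 <= x <= min(a0, b0)` in closed
#' form and returns the converted fraction `x / min(a0, b0)`.  With
#' `Keq = 81` and equimolar 10 mM substrates the conversion is exactly
#' 90%, the equilibrium scenario used to demonstrate genuine ornithine
#' turnover.
#'
#' @param keq Equilibrium constant (>= 0).
#' @param a0,b0 Initial substrate concentrations (mM, > 0).
#' @return Fraction of the limiting substrate converted, in \[0, 1\].
#' @export
equilibrium_conversion <- function(keq, a0, b0) {
  stopifnot(keq >= 0, a0 > 0, b0 > 0)
  if (keq == 0) return(0)
  if (!is.finite(keq)) return(1)
  lim <- min(a0, b0)
  # (1 - keq) x^2 + keq (a0 + b0) x - keq a0 b0 = 0
  A <- 1 - keq; B <- keq * (a0 + b0); C <- -keq * a0 * b0
  if (abs(A) < .Machine$double.eps * keq) {
    x <- a0 * b0 / (a0 + b0)
  } else {
    disc <- sqrt(B^2 - 4 * A * C)
    roots <- c((-B + disc) / (2 * A), (-B - disc) / (2 * A))
    ok <- roots[roots >= 0 & roots <= lim + 1e-12]
    if (length(ok) == 0L) stop("no physical root found", call. = FALSE)
    x <- min(ok)
  }
  min(x / lim, 1)
}

#' Read a two-column kinetics table
#'
#' Delimited text (whitespace, tab or comma) with two numeric columns:
#' concentration and rate (or percent activity).  Lines starting with `#`
#' and an optional non-numeric header row are skipped.
#'
#' @param path Path to the table.
#' @return data.frame with columns `concentration`, `value`.
#' @export
read_kinetics_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parse_row <- function(l) strsplit(trimws(l), "[,\t ]+")[[1]]
  rows <- lapply(lines, parse_row)
  first <- suppressWarnings(as.numeric(rows[[1]]))
  if (any(is.na(first))) rows <- rows[-1]
  vals <- vapply(rows, function(r) {
    x <- suppressWarnings(as.numeric(r[1:2]))
    if (any(is.na(x))) stop("non-numeric row in ", path, call. = FALSE)
    x
  }, numeric(2))
  data.frame(concentration = vals[1, ], value = vals[2, ])
}
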