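#' Biphasic (double-logistic) frontier curve
#'
#' Empirical rise-then-plateau-then-fall model for output along the
#' equal-staffing diagonal of a productivity surface:
#' \deqn{y(x) = t - \frac{A_{up}}{1 + B_{up} e^{x/C_{up} - D_{up}}}
#'            - \frac{A_{dn}}{1 + B_{dn} e^{-x/C_{dn} + D_{dn}}}.}
#' The first logistic releases output toward the plateau `t` as group size
#' `x` grows; the second takes it away again at large `x` where efficiency
#' losses dominate.
#'
#' @param x group sizes (e.g. number of chemists).
#' @param t plateau level.
#' @param Aup,Bup,Cup,Dup rising-limb amplitude, offset, scale and shift.
#' @param Adn,Bdn,Cdn,Ddn falling-limb amplitude, offset, scale and shift.
#' @return Predicted output values.
#' @export
#' @examples
#' biphasic(10, t = 0.802, Aup = 0.798, Bup = 1.971, Cup = 3.996, Dup = 2.402,
#'          Adn = 0.849, Bdn = 0.219, Cdn = 7.610, Ddn = 6.093)
biphasic <- function(x, t, Aup, Bup, Cup, Dup, Adn, Bdn, Cdn, Ddn) {
  t - Aup / (1 + Bup * exp(x / Cup - Dup)) -
    Adn / (1 + Bdn * exp(-x / Cdn + Ddn))
}

#' Fit the biphasic frontier model
#'
#' Least-squares fit of [biphasic()] to a diagonal productivity profile via
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]). Needs at least 10 points and
#' a finite initial guess; a degenerate profile (zero variance in `y`) or
#' non-convergence is reported as an error rather than silently returned.
#'
#' The conventional 9-parameter form is deliberately redundant: `Bup` and
#' `Dup` enter the model only through the product `Bup * exp(-Dup)`, and
#' `Bdn`/`Ddn` only through `Bdn * exp(Ddn)`, so just 7 parameter
#' combinations are identifiable from data. The fit is reported in the
#' familiar 9-parameter coordinates (which therefore depend on the starting
#' point along the redundant ridge), and the identifiable products are
#' returned separately as `identifiable`.
#'
#' @param x,y profile coordinates, e.g. from [frontier_diagonal()].
#' @param start named list/vector of starting values for `t, Aup, Bup, Cup,
#'   Dup, Adn, Bdn, Cdn, Ddn`.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @return A `biphasic_fit` object: `coefficients` (named, 9-parameter form),
#'   `identifiable` (t, Aup, Cup, kup = Bup*exp(-Dup), Adn, Cdn,
#'   kdn = Bdn*exp(Ddn)), `r_squared`, `fitted`, `residuals`, and the
#'   underlying [minpack.lm::nls.lm()] object as `fit`.
#' @export
#' @examples
#' truth <- list(t = 0.802, Aup = 0.798, Bup = 1.971, Cup = 3.996,
#'               Dup = 2.402, Adn = 0.849, Bdn = 0.219, Cdn = 7.610,
#'               Ddn = 6.093)
#' x <- seq(2, 40, by = 2)
#' y <- do.call(biphasic, c(list(x = x), truth))
#' fit_biphasic(x, y, start = truth)$r_squared
fit_biphasic <- function(x, y, start, max_iter = 500) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 10) stop("need at least 10 points to fit 9 parameters")
  start <- as.list(start)
  need <- c("t", "Aup", "Bup", "Cup", "Dup", "Adn", "Bdn", "Cdn", "Ddn")
  if (!all(need %in% names(start)))
    stop("start must name all of: ", paste(need, collapse = ", "))
  if (!all(is.finite(unlist(start[need])))) stop("initial guess must be finite")
  if (stats::var(y) == 0)
    stop("degenerate profile: y is constant, biphasic fit is not identifiable")
  resid_fn <- function(par) y - do.call(biphasic, c(list(x = x), as.list(par)))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = unlist(start[need]), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = max_iter)),
    error = function(e) stop("biphasic fit did not converge: ",
                             conditionMessage(e)))
  if (fit$info %in% c(0, 5, 9))
    stop("biphasic fit did not converge: ", fit$message)
  cf <- fit$par
  fitted <- y - resid_fn(cf)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    coefficients = cf,
    identifiable = c(t = unname(cf["t"]),
                     Aup = unname(cf["Aup"]), Cup = unname(cf["Cup"]),
                     kup = unname(cf["Bup"] * exp(-cf["Dup"])),
                     Adn = unname(cf["Adn"]), Cdn = unname(cf["Cdn"]),
                     kdn = unname(cf["Bdn"] * exp(cf["Ddn"]))),
    r_squared = 1 - ss_res / ss_tot,
    fitted = as.numeric(fitted),
    residuals = as.numeric(y - fitted),
    fit = fit
  ), class = "biphasic_fit")
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat("<biphasic_fit>  r^2 =", format(x$r_squared, digits = 4), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}
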