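#' FTE efficiency as a logistic in working-group size (A/B form)
#'
#' Full-time-equivalent (FTE) efficiency is the fraction of a scientist's time
#' spent on direct project work, as opposed to meetings, reports and other
#' coordination overhead that grows with the size of the working group. It is
#' modeled as a reversed logistic in group size `x`,
#' \deqn{E(x) = 1 / (1 + e^{x/A - B}),}
#' strictly decreasing, with `E = 0.5` exactly at `x = A*B` and `E -> 0` as
#' `x -> Inf`. `A` sets the decay rate and `B` the inflection point.
#'
#' @param x working-group size (scientists), `>= 0`; vectorised.
#' @param A,B positive logistic parameters.
#' @return Efficiency value(s) in (0, 1).
#' @seealso [efficiency_mn()] for the (M, N) parameterisation,
#'   [ab_from_mn()] for the conversion.
#' @export
#' @examples
#' ab <- ab_from_mn(40, 20)
#' efficiency_ab(40, ab$A, ab$B)   # 0.5 at x = A*B = M
efficiency_ab <- function(x, A, B) {
  if (!is.numeric(A) || length(A) != 1 || is.na(A) || A <= 0)
    stop("A must be a positive number")
  if (!is.numeric(B) || length(B) != 1 || is.na(B) || B <= 0)
    stop("B must be a positive number")
  if (any(x < 0)) stop("group size x must be >= 0")
  1 / (1 + exp(x / A - B))
}

#' Convert 50%/75% group sizes to logistic parameters
#'
#' The abstract logistic parameters are hard to estimate directly, so the
#' curve is parameterised instead by two interpretable group sizes: `M`, the
#' size at which efficiency has fallen to 50%, and `N`, the size at 75%.
#' Solving the logistic for these anchors gives
#' \deqn{A = (M - N) / 1.1, \quad B = M / A.}
#' The constant 1.1 is used literally (it approximates `log(3) = 1.0986`, so
#' the efficiency at `x = N` is 0.7503 rather than exactly 0.75).
#'
#' @param M group size at 50% efficiency; must exceed `N`.
#' @param N group size at 75% efficiency, positive.
#' @return `list(A =, B =)`.
#' @export
#' @examples
#' ab_from_mn(40, 20)   # A = 18.18..., B = 2.2
ab_from_mn <- function(M, N) {
  if (!is.numeric(M) || !is.numeric(N) || length(M) != 1 || length(N) != 1 ||
      is.na(M) || is.na(N))
    stop("M and N must be single numbers")
  if (N <= 0) stop("N must be positive")
  if (M <= N) stop("M must exceed N (group size at 50% efficiency must be ",
                   "larger than at 75%)")
  A <- (M - N) / 1.1
  list(A = A, B = M / A)
}

#' FTE efficiency as a logistic in working-group size (M/N form)
#'
#' Direct form of the efficiency curve in the interpretable parameters,
#' \deqn{E(x) = 1 / (1 + e^{1.1 (x - M) / (M - N)}),}
#' algebraically identical to [efficiency_ab()] with parameters from
#' [ab_from_mn()]. `E(M) = 0.5` exactly and `E(N) = 0.7503`.
#'
#' @param x working-group size (scientists), `>= 0`; vectorised.
#' @inheritParams ab_from_mn
#' @return Efficiency value(s) in (0, 1).
#' @export
#' @examples
#' efficiency_mn(36, 40, 20)   # efficiency of a 36-scientist group
efficiency_mn <- function(x, M, N) {
  ab <- ab_from_mn(M, N)  # validates M > N > 0
  if (any(x < 0)) stop("group size x must be >= 0")
  1 / (1 + exp(1.1 * (x - M) / (M - N)))
}

#' Resolve the FTE efficiency used in a simulation
#'
#' Returns the static `efficiency_override` when one is set in the parameters,
#' otherwise evaluates the logistic [efficiency_mn()] at the given group size
#' with the parameter set's `m50`/`n75`. The engine calls this once per run
#' with the total working-group size (`n_chemists + n_biologists`), which is
#' constant over a run.
#'
#' @param params a [pipeline_params()] object.
#' @param group_size group size at which to evaluate; defaults to the working
#'   group total.
#' @return A single efficiency value in (0, 1].
#' @export
#' @examples
#' resolve_efficiency(default_parameters())         # logistic at 36
#' resolve_efficiency(pipeline_params(efficiency_override = 0.8))
resolve_efficiency <- function(params,
                               group_size = params$n_chemists + params$n_biologists) {
  ov <- params$efficiency_override
  if (length(ov) == 1 && !is.na(ov)) return(as.numeric(ov))
  efficiency_mn(group_size, params$m50, params$n75)
}

#' Tabulate the efficiency curve
#'
#' Evaluates the (M, N) efficiency logistic over a grid of group sizes and
#' returns a two-column data frame, convenient for plotting or for export as
#' plain text.
#'
#' @inheritParams ab_from_mn
#' @param x group sizes at which to evaluate (default 0 to 100).
#' @param path optional path; when given, the table is also written as
#'   tab-separated text.
#' @return `data.frame(group_size, efficiency)`, invisibly when `path` is
#'   given.
#' @export
efficiency_curve <- function(M, N, x = 0:100, path = NULL) {
  curve <- data.frame(group_size = x, efficiency = efficiency_mn(x, M, N))
  if (!is.null(path)) {
    utils::write.table(curve, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(curve))
  }
  curve
}
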