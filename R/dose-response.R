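#' Four-parameter logistic function
#'
#' Evaluates \eqn{y = d + (a - d) / (1 + (x/c)^b)}. With \eqn{b > 0},
#' \eqn{a} is the low-dose (x -> 0) asymptote, \eqn{d} the high-dose
#' asymptote, and \eqn{c} the inflection concentration (the EC50):
#' \eqn{y(c) = (a + d) / 2}.
#'
#' @param x concentrations, > 0.
#' @param a low-dose asymptote (response scale).
#' @param b slope (dimensionless).
#' @param c inflection concentration (uM), > 0.
#' @param d high-dose asymptote.
#' @return numeric responses.
#' @examples
#' four_pl(0.6, a = 1, b = 1.5, c = 0.6, d = 2)  # (1 + 2) / 2
#' @export
four_pl <- function(x, a, b, c, d) {
  if (any(x <= 0)) stop("four_pl is defined for x > 0 only", call. = FALSE)
  d + (a - d) / (1 + (x / c)^b)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Nonlinear least squares (Levenberg-Marquardt, via
#' \code{minpack.lm::nlsLM}) of cFRET/donor (or any response) on
#' concentration under the four-parameter logistic model, reporting the
#' fitted inflection \code{c} as the EC50. Initialization: \code{d} = mean
#' response at the lowest dose, \code{a} = mean at the highest, \code{c} =
#' geometric mean of the dose range, \code{b} = 1; \code{c} is bounded in
#' (min dose / 10, max dose x 10). The fit is canonicalized to \code{b >
#' 0} with \code{a} as the low-dose asymptote (swapping \code{a}/\code{d}
#' and negating \code{b} leaves the curve unchanged), so the EC50 is
#' unique. Zero-dose (vehicle) rows must be excluded beforehand: the
#' model's \eqn{(x/c)^b} term is undefined at x = 0.
#'
#' @param concentration positive concentrations (uM), one per response.
#' @param response numeric responses.
#' @param weights optional per-observation weights (e.g. inverse
#'   replicate-variance); default unweighted.
#' @param tol convergence tolerance on parameters (default 1e-8).
#' @param max_iter maximum iterations (default 200).
#' @return object of class \code{four_pl_fit}: list with \code{coef}
#'   (named a, b, c, d), \code{ec50} (= \code{coef["c"]}), \code{rss},
#'   \code{converged}, \code{iterations}, \code{data}.
#' @examples
#' x <- rep(exp(seq(log(0.025), log(5), length.out = 8)), each = 3)
#' y <- four_pl(x, 1, 1.5, 0.6, 2)
#' fit_four_pl(x, y)$ec50
#' @export
fit_four_pl <- function(concentration, response, weights = NULL,
                        tol = 1e-8, max_iter = 200L) {
  if (length(concentration) != length(response)) {
    stop("concentration and response lengths differ", call. = FALSE)
  }
  if (any(concentration <= 0)) {
    stop("concentrations must be > 0; store vehicle rows separately",
         call. = FALSE)
  }
  if (any(!is.finite(response))) stop("responses must be finite", call. = FALSE)
  doses <- sort(unique(concentration))
  if (length(doses) < 4) {
    stop("need at least 4 distinct concentrations for a four-parameter fit ",
         "(got ", length(doses), "): fit is under-determined", call. = FALSE)
  }
  if (stats::var(response) == 0) {
    stop("responses are constant: fit is under-determined", call. = FALSE)
  }

  start <- list(
    a = mean(response[concentration == doses[1]]),
    b = 1,
    c = exp(mean(log(range(doses)))),
    d = mean(response[concentration == doses[length(doses)]])
  )
  # |b| capped at 50: steeper curves are numerically step functions and
  # unbounded slopes overflow (x/c)^b inside the optimizer.
  lower <- c(a = -Inf, b = -50, c = doses[1] / 10, d = -Inf)
  upper <- c(a = Inf, b = 50, c = doses[length(doses)] * 10, d = Inf)
  df <- data.frame(x = concentration, y = response)

  args <- list(
    y ~ d + (a - d) / (1 + (x / c)^b),
    data = df, start = start, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(
      ptol = tol, ftol = tol, maxiter = max_iter)
  )
  # nlsLM mishandles an explicit `weights = NULL`; only pass when given.
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(
      list(coef = c(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_),
           ec50 = NA_real_, rss = NA_real_, converged = FALSE,
           iterations = 0L, message = conditionMessage(fit), data = df),
      class = "four_pl_fit"
    ))
  }
  p <- stats::coef(fit)
  # Canonical orientation: b > 0, a = low-dose asymptote.
  if (p[["b"]] < 0) {
    p <- c(a = p[["d"]], b = -p[["b"]], c = p[["c"]], d = p[["a"]])
  }
  info <- fit$convInfo
  structure(
    list(coef = p[c("a", "b", "c", "d")], ec50 = unname(p[["c"]]),
         rss = sum(stats::residuals(fit)^2),
         converged = isTRUE(info$isConv) || is.null(info),
         iterations = if (!is.null(info$finIter)) info$finIter else NA_integer_,
         data = df),
    class = "four_pl_fit"
  )
}

#' Predict responses from a fitted four-parameter logistic curve
#'
#' @param object a \code{four_pl_fit}.
#' @param concentration positive concentrations (uM); defaults to the
#'   training concentrations.
#' @param ... unused.
#' @return numeric predicted responses.
#' @export
predict.four_pl_fit <- function(object, concentration = object$data$x, ...) {
  if (!object$converged) {
    stop("cannot predict from a non-converged fit", call. = FALSE)
  }
  p <- object$coef
  four_pl(concentration, p[["a"]], p[["b"]], p[["c"]], p[["d"]])
}

#' @export
print.four_pl_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Four-parameter logistic fit: NOT converged",
        if (!is.null(x$message)) paste0(" (", x$message, ")"), "\n", sep = "")
    return(invisible(x))
  }
  p <- x$coef
  cat(sprintf("Four-parameter logistic fit: EC50 = %.4g uM\n", x$ec50))
  cat(sprintf("  a = %.4g, b = %.4g, c = %.4g, d = %.4g; RSS = %.4g (%d obs)\n",
              p[["a"]], p[["b"]], p[["c"]], p[["d"]], x$rss, nrow(x$data)))
  invisible(x)
}

#' Fit dose-response curves from a long-format table
#'
#' Convenience wrapper applying [fit_four_pl()] per compound on a table
#' with columns \code{compound_id}, \code{concentration_um},
#' \code{response} (replicate rows enter the fit as independent
#' observations).
#'
#' @param doses long-format dose-response data.frame.
#' @param ... passed to [fit_four_pl()].
#' @return named list of \code{four_pl_fit} objects, one per compound.
#' @export
fit_dose_table <- function(doses, ...) {
  need <- c("compound_id", "concentration_um", "response")
  miss <- setdiff(need, names(doses))
  if (length(miss)) {
    stop("dose table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(doses, doses$compound_id), function(sub) {
    fit_four_pl(sub$concentration_um, sub$response, ...)
  })
}
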