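#' Distribution law specifications
#'
#' A "law" is a small list describing a univariate sampling distribution used
#' by the synthetic cohort generator for per-organoid quantities (baseline
#' diameter, percent growth, baseline ORR, change in ORR). Supported families:
#'
#' * `"normal"`: parameters `mean`, `sd`.
#' * `"lognormal"`: parameters `median` (on the natural scale) and `sdlog`.
#' * `"uniform"`: parameters `min`, `max`.
#' * `"constant"`: parameter `value`.
#'
#' @param family One of `"normal"`, `"lognormal"`, `"uniform"`, `"constant"`.
#' @param ... Named numeric parameters for the family (see above).
#' @return An object of class `"org_law"`.
#' @examples
#' law("normal", mean = 64, sd = 56.6)
#' law("lognormal", median = 200, sdlog = 0.2)
#' @export
law <- function(family = c("normal", "lognormal", "uniform", "constant"), ...) {
  family <- match.arg(family)
  pars <- list(...)
  need <- switch(family,
    normal = c("mean", "sd"),
    lognormal = c("median", "sdlog"),
    uniform = c("min", "max"),
    constant = "value"
  )
  missing <- setdiff(need, names(pars))
  if (length(missing)) {
    stop("law('", family, "') requires parameter(s): ",
         paste(missing, collapse = ", "))
  }
  structure(list(family = family, pars = pars[need]), class = "org_law")
}

#' Sample from a law
#'
#' @param x An [law()] object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_law <- function(x, n) {
  stopifnot(inherits(x, "org_law"), n >= 0)
  p <- x$pars
  switch(x$family,
    normal = stats::rnorm(n, p$mean, p$sd),
    lognormal = stats::rlnorm(n, meanlog = log(p$median), sdlog = p$sdlog),
    uniform = stats::runif(n, p$min, p$max),
    constant = rep(p$value, n)
  )
}

#' Theoretical median of a law
#'
#' @param x An [law()] object.
#' @return The population median.
#' @export
law_median <- function(x) {
  stopifnot(inherits(x, "org_law"))
  p <- x$pars
  switch(x$family,
    normal = p$mean,
    lognormal = p$median,
    uniform = (p$min + p$max) / 2,
    constant = p$value
  )
}

#' @export
print.org_law <- function(x, ...) {
  cat("<law ", x$family, ": ",
      paste(names(x$pars), unlist(x$pars), sep = "=", collapse = ", "),
      ">\n", sep = "")
  invisible(x)
}

# Deterministic child seed from a master seed and a stream index.
# Keeps results below 2^31 so set.seed() always accepts them.
child_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + as.numeric(index) * 104729) %% 2147483629)
}
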