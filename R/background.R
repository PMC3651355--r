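#' Background model parameters
#'
#' Parameters of the observation model `observed = background + signal`
#' with `background ~ Normal(mu, sigma^2)` (truncated at zero in
#' practice) and `signal ~ Exponential(alpha)`.
#'
#' @param mu Background mean, linear intensity units.
#' @param sigma Background standard deviation, linear intensity units
#'   (> 0).
#' @param alpha Signal exponential rate, 1/intensity units (> 0).
#' @return An object of class `bg_params`.
#' @export
bg_params <- function(mu, sigma, alpha) {
  stopifnot(is.finite(mu), is.finite(sigma), is.finite(alpha),
            sigma > 0, alpha > 0)
  structure(list(mu = mu, sigma = sigma, alpha = alpha),
            class = "bg_params")
}

#' @export
print.bg_params <- function(x, ...) {
  cat(sprintf("Background model: mu = %.4g, sigma = %.4g, alpha = %.6g\n",
              x$mu, x$sigma, x$alpha))
  invisible(x)
}

# log density of the normal + exponential convolution
# f(o) = alpha * exp(alpha*(mu - o) + alpha^2 sigma^2 / 2) * Phi((o - mu - sigma^2 alpha)/sigma)
convolution_logdens <- function(o, mu, sigma, alpha) {
  log(alpha) + alpha * (mu - o) + 0.5 * (alpha * sigma)^2 +
    stats::pnorm((o - mu - sigma^2 * alpha) / sigma, log.p = TRUE)
}

# z* solving phi(z)/Phi(z) = r: the standardized offset of the
# convolution mode above mu + sigma^2*alpha
mills_inverse <- function(r) {
  if (r <= 0) return(Inf)
  f <- function(z) exp(stats::dnorm(z, log = TRUE) -
                         stats::pnorm(z, log.p = TRUE)) - r
  stats::uniroot(f, lower = -40, upper = 40, tol = 1e-10)$root
}

kde_mode <- function(x) {
  d <- stats::density(x, bw = "nrd0", n = 2048)
  d$x[which.max(d$y)]
}

#' Estimate background parameters for one chip
#'
#' Fits the normal-plus-exponential observation model to a vector of
#' linear intensities.  Initialization follows the classical
#' mode-and-moments recipe: the mode of a kernel density estimate over
#' the lower half of the data locates the bulk of the background, the
#' spread of values below the mode gives a reflected-half sigma, and
#' the reciprocal mean excess above the mode gives alpha.  Because the
#' mode of the convolution sits above the background mean by
#' `sigma^2*alpha + sigma*z*` (with `phi(z*)/Phi(z*) = alpha*sigma`),
#' the initial mu is bias-corrected by inverting that relation, and all
#' three parameters are then refined by maximum likelihood on the
#' closed-form convolution density.
#'
#' @param chip Numeric vector of linear intensities (length >= 100,
#'   values > 0).
#' @param refine Run the likelihood refinement step (default TRUE).
#' @return A [bg_params()] object.
#' @examples
#' set.seed(1)
#' x <- pmax(rnorm(5000, 100, 15), 0) + rexp(5000, 0.005)
#' estimate_bg_params(x)
#' @export
estimate_bg_params <- function(chip, refine = TRUE) {
  chip <- as.numeric(chip)
  if (length(chip) < 100) stop("need at least 100 intensities to estimate background")
  if (any(!is.finite(chip)) || any(chip <= 0)) {
    stop("background estimation requires finite, positive intensities")
  }
  if (stats::sd(chip) == 0) stop("cannot estimate background from a constant chip")

  lower <- chip[chip <= stats::median(chip)]
  mode0 <- kde_mode(lower)

  below <- chip[chip < mode0]
  if (length(below) < 10) below <- utils::head(sort(chip), 10)
  sigma0 <- sqrt(mean((below - mode0)^2))
  above <- chip[chip > mode0]
  alpha0 <- 1 / mean(above - mode0)

  # invert the analytic mode location to de-bias mu
  mu0 <- mode0 - sigma0^2 * alpha0 - sigma0 * mills_inverse(alpha0 * sigma0)

  par <- c(mu = mu0, log_sigma = log(sigma0), log_alpha = log(alpha0))
  if (refine) {
    nll <- function(p) {
      v <- -sum(convolution_logdens(chip, p[1], exp(p[2]), exp(p[3])))
      if (!is.finite(v)) .Machine$double.xmax else v
    }
    # box constraints keep the fit off the degenerate ridge the
    # convolution likelihood has when one component vanishes
    lo <- c(mu0 - 5 * sigma0, log(sigma0) - log(10), log(alpha0) - log(100))
    hi <- c(mu0 + 5 * sigma0, log(sigma0) + log(10), log(alpha0) + log(100))
    opt <- try(stats::optim(par, nll, method = "L-BFGS-B",
                            lower = lo, upper = hi,
                            control = list(maxit = 200)), silent = TRUE)
    if (!inherits(opt, "try-error") && is.finite(opt$value)) par <- opt$par
  }
  bg_params(mu = unname(par[1]),
            sigma = exp(unname(par[2])),
            alpha = exp(unname(par[3])))
}

#' Background-correct one chip
#'
#' Returns the conditional expectation of the signal given the observed
#' intensity under the normal-plus-exponential convolution model: with
#' `a = o - mu - sigma^2*alpha` and `b = sigma`, the corrected value is
#' `a + b*phi(a/b)/Phi(a/b)`.  The inverse Mills ratio is evaluated
#' through the log-CDF so the expression stays finite far below the
#' background.  The correction is strictly positive and strictly
#' increasing in the observed intensity, so per-chip rank order is
#' preserved.
#'
#' @param chip Numeric vector of linear intensities.
#' @param params A [bg_params()] object.
#' @return Corrected intensity vector, same length, all values > 0.
#' @export
correct_chip <- function(chip, params) {
  stopifnot(inherits(params, "bg_params"))
  a <- chip - params$mu - params$sigma^2 * params$alpha
  z <- a / params$sigma
  mills <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
  a + params$sigma * mills
}

#' Background-subtract every sample of a matrix
#'
#' Each sample column is corrected independently with its own estimated
#' parameters; the result for a column never depends on which other
#' columns are present.
#'
#' @param matrix A linear-scale [expression_matrix()].
#' @param refine Passed to [estimate_bg_params()].
#' @return A list with `matrix` (the corrected [expression_matrix()])
#'   and `params` (named list of per-sample [bg_params()]).
#' @export
background_subtract <- function(matrix, refine = TRUE) {
  assert_scale(matrix, "linear")
  out <- unclass(matrix)
  params <- vector("list", ncol(matrix))
  names(params) <- colnames(matrix)
  for (j in seq_len(ncol(matrix))) {
    p <- tryCatch(
      estimate_bg_params(pseudo_positive(out[, j]), refine = refine),
      error = function(e) {
        stop("background estimation failed for sample '",
             colnames(matrix)[j], "': ", conditionMessage(e), call. = FALSE)
      })
    params[[j]] <- p
    out[, j] <- correct_chip(out[, j], p)
  }
  list(matrix = expression_matrix(out, scale = "linear"), params = params)
}
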