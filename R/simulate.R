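#' Distortion library
#'
#' Strictly increasing response-curve distortions used by the
#' synthetic-data generator to emulate nonlinear signal response
#' differences between chips.
#'
#' * `identity`: `f(x) = x`.
#' * `gain`: `f(x) = c * x` (constant multiplicative gain).
#' * `gamma_curve`: `f(x) = x^g`, rescaled so the median of the vector
#'   it is applied to is preserved (`f(x) = x^g * med^(1-g)`).
#' * `smooth_spline_warp`: a monotone (Hyman-filtered) cubic spline
#'   through log-log anchor points jittered by `jitter_sd` log2 units;
#'   a jitter that breaks monotonicity of the anchors is an error.
#'
#' @param name One of `"identity"`, `"gain"`, `"gamma_curve"`,
#'   `"smooth_spline_warp"`.
#' @param gain Gain factor (for `gain`).
#' @param g Exponent (for `gamma_curve`).
#' @param anchors Positive, strictly increasing anchor intensities (for
#'   `smooth_spline_warp`); default spans 1 to 2^17.
#' @param jitter Log2 offsets added to the anchor outputs, one per
#'   anchor (for `smooth_spline_warp`).
#' @return A function mapping positive intensity vectors to positive
#'   intensity vectors, strictly increasing.
#' @examples
#' f <- make_distortion("gamma_curve", g = 1.2)
#' all(diff(f(c(10, 100, 1000))) > 0)
#' @export
make_distortion <- function(name = c("identity", "gain", "gamma_curve",
                                     "smooth_spline_warp"),
                            gain = 1, g = 1,
                            anchors = 2^seq(0, 17, by = 1.7),
                            jitter = NULL) {
  name <- match.arg(name)
  f <- switch(name,
    identity = function(x) x,
    gain = {
      stopifnot(gain > 0)
      force(gain)
      function(x) gain * x
    },
    gamma_curve = {
      stopifnot(g > 0)
      force(g)
      function(x) {
        m <- stats::median(x)
        x^g * m^(1 - g)
      }
    },
    smooth_spline_warp = {
      stopifnot(all(anchors > 0), all(diff(anchors) > 0))
      if (is.null(jitter)) jitter <- rep(0, length(anchors))
      stopifnot(length(jitter) == length(anchors))
      la <- log2(anchors)
      lo <- la + jitter
      if (any(diff(lo) <= 0)) {
        stop("jittered anchor set is not strictly increasing")
      }
      sf <- stats::splinefun(la, lo, method = "hyman")
      function(x) 2^sf(log2(x))
    })
  attr(f, "distortion") <- name
  f
}

#' Specification of a synthetic chip set
#'
#' Defines the generative model for [simulate_chip_set()].  Probeset
#' latent expression is log-normal, probe affinity multiplicative
#' log-normal, and every probe additionally carries an exponential
#' signal component, so the per-chip observed intensities follow the
#' additive normal background + exponentially distributed signal
#' structure the background model assumes.  Per chip, the true signal
#' is perturbed by a small multiplicative log-normal measurement noise,
#' passed through the chip's distortion curve, shifted on designated
#' "arm" chips, and offset by an independently drawn truncated-normal
#' background, with a saturation ceiling applied last.
#'
#' @param n_probes Number of probes.
#' @param n_probesets Number of probesets (`probes_per_set *
#'   n_probesets` must equal `n_probes`).
#' @param probes_per_set Probes per probeset.
#' @param n_chips Number of chips.
#' @param bg_mu,bg_sigma Background normal parameters (linear units).
#' @param signal_rate Rate of the additive exponential signal
#'   component.
#' @param latent_meanlog,latent_sdlog Log-normal parameters of the
#'   latent probeset expression.
#' @param affinity_sdlog Log-normal sdlog of the multiplicative probe
#'   affinity.
#' @param noise_sd_log2 Per-chip multiplicative measurement noise, log2
#'   standard deviation.
#' @param distortion A single distortion function (recycled), or a list
#'   with one function per chip (see [make_distortion()]); `NULL` means
#'   identity for every chip.
#' @param arm_fraction Fraction of probes placed in the
#'   uni-directionally shifted differential-expression arm.
#' @param arm_log2_shift Length-2 range; each arm probe's log2 shift is
#'   drawn uniformly from it.
#' @param arm_chips Chip indices on which the arm shift is applied
#'   (default: every chip except the first).
#' @param saturation_cap Ceiling applied to observed intensities.
#' @param seed Integer seed; the same seed always reproduces the same
#'   chip set.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_probes = 10000, n_probesets = 2000,
                     probes_per_set = 5, n_chips = 2,
                     bg_mu = 100, bg_sigma = 15, signal_rate = 0.005,
                     latent_meanlog = log(500), latent_sdlog = 2,
                     affinity_sdlog = 0.4, noise_sd_log2 = 0.02,
                     distortion = NULL,
                     arm_fraction = 0, arm_log2_shift = c(1, 3),
                     arm_chips = NULL,
                     saturation_cap = 64000, seed = 1) {
  spec <- list(n_probes = as.integer(n_probes),
               n_probesets = as.integer(n_probesets),
               probes_per_set = as.integer(probes_per_set),
               n_chips = as.integer(n_chips),
               bg_mu = bg_mu, bg_sigma = bg_sigma,
               signal_rate = signal_rate,
               latent_meanlog = latent_meanlog,
               latent_sdlog = latent_sdlog,
               affinity_sdlog = affinity_sdlog,
               noise_sd_log2 = noise_sd_log2,
               distortion = distortion,
               arm_fraction = arm_fraction,
               arm_log2_shift = arm_log2_shift,
               arm_chips = if (is.null(arm_chips) && n_chips > 1)
                 seq.int(2L, n_chips) else as.integer(arm_chips),
               saturation_cap = saturation_cap,
               seed = as.integer(seed))
  with(spec, stopifnot(
    n_probes > 0, n_chips >= 1,
    arm_fraction >= 0, arm_fraction < 1,
    bg_sigma >= 0, signal_rate > 0, saturation_cap > 0,
    noise_sd_log2 >= 0,
    length(arm_log2_shift) == 2, arm_log2_shift[1] <= arm_log2_shift[2]
  ))
  if (spec$probes_per_set * spec$n_probesets != spec$n_probes) {
    stop("infeasible spec: probes_per_set * n_probesets (",
         spec$probes_per_set * spec$n_probesets,
         ") must equal n_probes (", spec$n_probes, ")")
  }
  class(spec) <- "sim_spec"
  spec
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

resolve_distortions <- function(spec) {
  d <- spec$distortion
  n <- spec$n_chips
  if (is.null(d)) d <- make_distortion("identity")
  if (is.function(d)) d <- rep(list(d), n)
  stopifnot(length(d) == n, all(vapply(d, is.function, logical(1))))
  d
}

#' Simulate a chip set with known ground truth
#'
#' Draws latent probeset expression once, probe effects per probe, and
#' generates each chip's observed intensities as
#' `distortion(signal * 2^(arm shift) * 2^noise) + background`, clipped
#' at the saturation ceiling.  Truth tables record every latent
#' quantity needed to compute recovery metrics.
#'
#' @param spec A [sim_spec()].
#' @return A list with `matrix` (linear [expression_matrix()]),
#'   `layout` ([chip_layout()]), and `truth`: a list with `probes`
#'   (data frame: probe, probeset, signal, arm, arm_shift), `chips`
#'   (data frame: chip, distortion name, arm applied), and the `spec`.
#' @examples
#' sim <- simulate_chip_set(sim_spec(n_probes = 100, n_probesets = 50,
#'   probes_per_set = 2, n_chips = 2, seed = 7))
#' dim(sim$matrix)
#' @export
simulate_chip_set <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  dists <- resolve_distortions(spec)
  with_seed(spec$seed, {
    n <- spec$n_probes
    ps_id <- paste0("ps", formatC(seq_len(spec$n_probesets), width = 6,
                                  flag = "0"))
    probe_ps <- rep(ps_id, each = spec$probes_per_set)
    probe_id <- paste0("p", formatC(seq_len(n), width = 7, flag = "0"))

    latent <- stats::rlnorm(spec$n_probesets, spec$latent_meanlog,
                            spec$latent_sdlog)
    affinity <- stats::rlnorm(n, 0, spec$affinity_sdlog)
    expo <- stats::rexp(n, spec$signal_rate)
    signal <- latent[rep(seq_len(spec$n_probesets),
                         each = spec$probes_per_set)] * affinity + expo

    arm <- stats::runif(n) < spec$arm_fraction
    shift <- numeric(n)
    shift[arm] <- stats::runif(sum(arm), spec$arm_log2_shift[1],
                               spec$arm_log2_shift[2])

    out <- matrix(0, n, spec$n_chips,
                  dimnames = list(probe_id,
                                  paste0("chip", sprintf("%02d",
                                                         seq_len(spec$n_chips)))))
    for (j in seq_len(spec$n_chips)) {
      s <- signal
      if (j %in% spec$arm_chips) s <- s * 2^shift
      if (spec$noise_sd_log2 > 0) {
        s <- s * 2^stats::rnorm(n, 0, spec$noise_sd_log2)
      }
      s <- dists[[j]](s)
      bgv <- if (spec$bg_sigma > 0) {
        pmax(stats::rnorm(n, spec$bg_mu, spec$bg_sigma), 0)
      } else {
        rep(spec$bg_mu, n)
      }
      out[, j] <- pmin(s + bgv, spec$saturation_cap)
    }

    layout <- chip_layout(probe_id, probe_ps)
    truth <- list(
      probes = data.frame(probe = probe_id, probeset = probe_ps,
                          signal = signal, arm = arm, arm_shift = shift,
                          stringsAsFactors = FALSE),
      chips = data.frame(
        chip = colnames(out),
        distortion = vapply(dists, function(f) {
          a <- attr(f, "distortion"); if (is.null(a)) "custom" else a
        }, character(1)),
        arm_applied = seq_len(spec$n_chips) %in% spec$arm_chips,
        stringsAsFactors = FALSE),
      spec = spec)
    list(matrix = expression_matrix(out, scale = "linear"),
         layout = layout,
         truth = truth)
  })
}

#' Warped technical replicate of an observed chip
#'
#' Produces a distorted re-measurement of an existing chip: the
#' observed intensities are passed through a strictly increasing
#' response curve, optionally shifted on a designated arm of features,
#' and perturbed by multiplicative log-normal measurement noise.  This
#' construction gives a pair whose only systematic difference is the
#' known distortion, the setting in which a normalization's recovery of
#' the undistorted chip can be measured directly.
#'
#' @param chip Named or unnamed vector of positive linear intensities.
#' @param distortion A distortion function from [make_distortion()]
#'   (default identity).
#' @param noise_sd_log2 Log2 sd of the multiplicative measurement
#'   noise.
#' @param arm Logical vector marking arm features (default none).
#' @param arm_shift Log2 shift per feature (scalar or vector; applied
#'   where `arm` is TRUE).
#' @param seed Integer seed for the noise draw.
#' @return Intensity vector of the warped replicate.
#' @export
warp_chip <- function(chip, distortion = make_distortion("identity"),
                      noise_sd_log2 = 0.02, arm = NULL, arm_shift = 2,
                      seed = 1) {
  stopifnot(all(chip > 0), is.function(distortion))
  with_seed(seed, {
    s <- chip
    if (!is.null(arm)) {
      stopifnot(length(arm) == length(chip))
      shift <- rep_len(arm_shift, length(chip))
      s[arm] <- s[arm] * 2^shift[arm]
    }
    if (noise_sd_log2 > 0) {
      s <- s * 2^stats::rnorm(length(s), 0, noise_sd_log2)
    }
    out <- distortion(s)
    names(out) <- names(chip)
    out
  })
}
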