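#' Joint waveform template
#'
#' Parametric description of the noise-free vertical-displacement waveform of
#' one joint over a single step cycle, in arbitrary units (AU). Two shapes
#' cover the patterns seen in walking rodents:
#'
#' * `"unidirectional"` — a single excursion (one interior extremum), a
#'   raised-cosine bump peaking at `phase_peak`; the shape of the rat
#'   metatarsus/ankle and the mouse knee.
#' * `"pendular"` — two opposite-direction excursions within one cycle
#'   (a positive extremum at `phase_peak`, a negative one at
#'   `second_extremum_bin`), realised as a single-period sine under a
#'   monotone time warp; the shape of the mouse metatarsus/ankle and the
#'   rat knee.
#'
#' With `amplitude = 0` either pattern degenerates to the constant
#' `baseline`.
#'
#' @param pattern `"unidirectional"` or `"pendular"`.
#' @param amplitude Peak excursion from baseline, AU, `>= 0`.
#' @param baseline Resting level, AU.
#' @param phase_peak Cycle bin (on the 1..100 scale) of the (first, positive)
#'   extremum; must be interior, i.e. in `[2, 99]`.
#' @param second_extremum_bin Pendular only: cycle bin of the opposite-sign
#'   extremum; interior and strictly greater than `phase_peak`.
#' @return An object of class `waveform_template`.
#' @seealso [render_template()], [apply_lesion_effect()]
#' @examples
#' tpl <- waveform_template("unidirectional", amplitude = 1, baseline = 0,
#'                          phase_peak = 50)
#' v <- render_template(tpl, 100)
#' which.max(v) # 50
#' @export
waveform_template <- function(pattern, amplitude, baseline = 0,
                              phase_peak = 50, second_extremum_bin = NULL) {
  pattern <- match.arg(pattern, c("unidirectional", "pendular"))
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude),
            is.numeric(baseline), length(baseline) == 1L, is.finite(baseline))
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (!is.numeric(phase_peak) || length(phase_peak) != 1L ||
      phase_peak < 2 || phase_peak > 99) {
    stop("phase_peak must be an interior cycle bin in [2, 99]", call. = FALSE)
  }
  if (pattern == "pendular") {
    if (is.null(second_extremum_bin)) {
      stop("pendular template requires second_extremum_bin", call. = FALSE)
    }
    if (!is.numeric(second_extremum_bin) || length(second_extremum_bin) != 1L ||
        second_extremum_bin <= phase_peak || second_extremum_bin > 99) {
      stop("second_extremum_bin must lie in (phase_peak, 99]", call. = FALSE)
    }
  } else {
    second_extremum_bin <- NULL
  }
  structure(
    list(pattern = pattern, amplitude = amplitude, baseline = baseline,
         phase_peak = phase_peak, second_extremum_bin = second_extremum_bin),
    class = "waveform_template"
  )
}

#' @export
print.waveform_template <- function(x, ...) {
  cat(sprintf("<waveform_template> %s: amplitude %.3g AU, baseline %.3g AU, peak at bin %g",
              x$pattern, x$amplitude, x$baseline, x$phase_peak))
  if (!is.null(x$second_extremum_bin)) {
    cat(sprintf(", second extremum at bin %g", x$second_extremum_bin))
  }
  cat("\n")
  invisible(x)
}

# piecewise-linear monotone warp through the given (u, g) knots
pwl_warp <- function(u, knots_u, knots_g) {
  stats::approx(knots_u, knots_g, xout = u, rule = 2)$y
}

# continuous waveform as a function of normalized cycle time u in [0, 1];
# used both for rendering at bins and for frame-time sampling in the
# synthetic generator
template_value <- function(template, u) {
  if (template$amplitude == 0) {
    return(rep(template$baseline, length(u)))
  }
  u_pk <- (template$phase_peak - 1) / 99
  if (template$pattern == "unidirectional") {
    g <- pwl_warp(u, c(0, u_pk, 1), c(0, 0.5, 1))
    template$baseline + template$amplitude * sin(pi * g)^2
  } else {
    u2 <- (template$second_extremum_bin - 1) / 99
    g <- pwl_warp(u, c(0, u_pk, u2, 1), c(0, 0.25, 0.75, 1))
    template$baseline + template$amplitude * sin(2 * pi * g)
  }
}

#' Render a waveform template at cycle bins
#'
#' Evaluates the noise-free template at `n_bins` equally spaced points of the
#' step cycle (bin `i` maps to normalized time `(i - 1) / (n_bins - 1)`).
#' Deterministic in its inputs.
#'
#' @param template A [waveform_template()].
#' @param n_bins Number of cycle bins, `>= 2`; the analysis convention is 100.
#' @return Numeric vector of length `n_bins`, AU.
#' @export
render_template <- function(template, n_bins = 100L) {
  stopifnot(inherits(template, "waveform_template"))
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 2) {
    stop("n_bins must be >= 2", call. = FALSE)
  }
  u <- (seq_len(n_bins) - 1) / (n_bins - 1)
  template_value(template, u)
}

#' Localized lesion effect on a step-cycle waveform
#'
#' Ground-truth mechanism of the synthetic generator: a signed vertical
#' shift `delta` applied to cycle bins `bin_start..bin_end`, optionally
#' ramped in and out over a fraction `taper` of the affected span so the
#' shift enters smoothly. `delta = 0` is the identity.
#'
#' @param bin_start,bin_end First and last affected cycle bin, in `[1, 100]`
#'   with `bin_end >= bin_start`.
#' @param delta Signed vertical shift, AU.
#' @param taper Fraction in `[0, 1]` of the affected span used for the
#'   raised-cosine ramp-in/out (half at each end); `0` means a hard step.
#' @return An object of class `lesion_effect`.
#' @seealso [apply_lesion_effect()]
#' @export
lesion_effect <- function(bin_start, bin_end, delta, taper = 0) {
  stopifnot(is.numeric(bin_start), is.numeric(bin_end), is.numeric(delta),
            is.numeric(taper), length(taper) == 1L)
  if (bin_start < 1 || bin_start > 100 || bin_end < bin_start || bin_end > 100) {
    stop("lesion bins must satisfy 1 <= bin_start <= bin_end <= 100",
         call. = FALSE)
  }
  if (taper < 0 || taper > 1) stop("taper must be in [0, 1]", call. = FALSE)
  structure(
    list(bin_start = as.integer(bin_start), bin_end = as.integer(bin_end),
         delta = delta, taper = taper),
    class = "lesion_effect"
  )
}

#' @export
print.lesion_effect <- function(x, ...) {
  cat(sprintf("<lesion_effect> bins %d..%d (%d bins), delta %.3g AU, taper %.2f\n",
              x$bin_start, x$bin_end, x$bin_end - x$bin_start + 1L,
              x$delta, x$taper))
  invisible(x)
}

# per-bin weights of the effect over its affected span
lesion_weights <- function(effect) {
  span <- effect$bin_end - effect$bin_start + 1L
  w <- rep(1, span)
  ramp <- floor(effect$taper * span / 2)
  if (ramp > 0) {
    k <- seq_len(ramp)
    edge <- (1 - cos(pi * k / (ramp + 1))) / 2
    w[k] <- edge
    w[span + 1L - k] <- edge
  }
  w
}

#' Apply a lesion effect to a bin-indexed series
#'
#' Shifts the affected bins of a 100-bin step-cycle series by the effect's
#' `delta` (times the taper weight); all other bins are returned unchanged.
#'
#' @param series Numeric vector of length 100 (one value per cycle bin).
#' @param effect A [lesion_effect()].
#' @return Numeric vector of length 100.
#' @export
apply_lesion_effect <- function(series, effect) {
  stopifnot(inherits(effect, "lesion_effect"))
  if (!is.numeric(series) || length(series) != 100L) {
    stop("series must be a numeric vector of length 100", call. = FALSE)
  }
  idx <- effect$bin_start:effect$bin_end
  out <- series
  out[idx] <- out[idx] + effect$delta * lesion_weights(effect)
  out
}

# continuous-time version for frame sampling: effect weight at normalized
# cycle time u, linearly interpolated between bin centres
lesion_value <- function(effect, u) {
  if (is.null(effect) || effect$delta == 0) return(rep(0, length(u)))
  w_bins <- numeric(100)
  w_bins[effect$bin_start:effect$bin_end] <- lesion_weights(effect)
  u_bins <- (0:99) / 99
  effect$delta * stats::approx(u_bins, w_bins, xout = u, rule = 2)$y
}
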