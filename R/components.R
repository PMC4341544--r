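# ERP component templates: Gaussian time course x scalp topography x
# per-condition amplitude.

#' Define an ERP component template
#'
#' A component contributes
#' `amplitude[condition] * exp(-((t - peak)/width)^2 / 2) * topography[channel]`
#' microvolts to every trial of a condition (scaled by the subject gain).
#' Negative amplitudes encode negativities (N250, N400), positive ones
#' positivities (P325).
#'
#' @param name Label, e.g. `"N400"`.
#' @param peak_latency_ms Peak latency in ms relative to target onset.
#' @param width_ms Temporal SD of the Gaussian envelope in ms; must be > 0.
#' @param amplitude Named numeric vector, one amplitude in microvolts per
#'   condition in the design.
#' @param topography Named numeric vector of unitless channel weights in
#'   `[0, 1]`; channels absent from the vector get weight 0 (raw channels of
#'   a pooled montage inherit their pool's weight, see [simulate_epochs()]).
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(name, peak_latency_ms, width_ms, amplitude,
                           topography) {
  if (!is.numeric(width_ms) || width_ms <= 0) {
    stop("width_ms must be positive", call. = FALSE)
  }
  if (is.null(names(amplitude)) || any(!nzchar(names(amplitude)))) {
    stop("amplitude must be a named vector (one entry per condition)",
         call. = FALSE)
  }
  if (any(topography < 0 | topography > 1)) {
    stop("topography weights must lie in [0, 1]", call. = FALSE)
  }
  structure(list(name = name, peak_latency_ms = peak_latency_ms,
                 width_ms = width_ms, amplitude = amplitude,
                 topography = topography),
            class = "component_spec")
}

#' Canonical scalp topographies over the 19 pooled channels
#'
#' Smooth unitless weight maps used by the default components: a
#' centro-parietal map peaking at CPz/Pz (N400-like), a central map peaking
#' at Cz/FCz, and a right-frontal map peaking at F6/FC6 (form effects).
#'
#' @param kind One of `"centroparietal"`, `"central"`, `"frontal_right"`.
#' @return Named numeric vector over [standard_channels()].
#' @export
scalp_topography <- function(kind = c("centroparietal", "central",
                                      "frontal_right")) {
  kind <- match.arg(kind)
  w <- switch(kind,
    centroparietal = c(Fpz = 0.05, AFz = 0.10, F5 = 0.15, Fz = 0.25, F6 = 0.15,
                       FC5 = 0.35, FCz = 0.55, FC6 = 0.35,
                       C5 = 0.55, Cz = 0.85, C6 = 0.55,
                       CP5 = 0.70, CPz = 1.00, CP6 = 0.70,
                       P5 = 0.65, Pz = 0.95, P6 = 0.65,
                       POz = 0.60, Oz = 0.35),
    central = c(Fpz = 0.10, AFz = 0.25, F5 = 0.30, Fz = 0.55, F6 = 0.30,
                FC5 = 0.55, FCz = 0.90, FC6 = 0.55,
                C5 = 0.60, Cz = 1.00, C6 = 0.60,
                CP5 = 0.50, CPz = 0.80, CP6 = 0.50,
                P5 = 0.30, Pz = 0.50, P6 = 0.30,
                POz = 0.25, Oz = 0.10),
    frontal_right = c(Fpz = 0.55, AFz = 0.60, F5 = 0.25, Fz = 0.55, F6 = 1.00,
                      FC5 = 0.15, FCz = 0.45, FC6 = 0.85,
                      C5 = 0.05, Cz = 0.25, C6 = 0.50,
                      CP5 = 0.00, CPz = 0.10, CP6 = 0.25,
                      P5 = 0.00, Pz = 0.05, P6 = 0.10,
                      POz = 0.00, Oz = 0.00))
  w[standard_channels()]
}

#' Default component set emulating the priming effects
#'
#' Four components reproduce the qualitative result pattern of the study
#' conditions: an N250 and a strong centro-parietal N400 whose amplitudes are
#' most negative for unrelated primes and attenuate with relatedness (rank
#' order of N400 negativity T = O < S < F < U), a P325 positivity enhanced
#' for morphological primes, and an early right-frontal positivity for
#' form-related primes. Amplitudes are in microvolts at the topography peak.
#'
#' @param effect_scale Multiplier on all between-condition amplitude
#'   differences; `effect_scale = 0` collapses every condition onto the
#'   unrelated baseline (null data with realistic waveforms).
#' @return List of [component_spec()] objects.
#' @export
default_components <- function(effect_scale = 1) {
  conds <- all_conditions()
  amp <- function(base, by) {
    out <- rep(base, length(conds))
    names(out) <- conds
    out[names(by)] <- base + effect_scale * (by - base)
    out
  }
  list(
    component_spec("N250", 250, 25,
                   amp(-2.0, c(S = -1.8, T = -0.8, O = -0.8, F = -1.2)),
                   scalp_topography("centroparietal")),
    component_spec("P325", 325, 30,
                   amp(0.3, c(S = 0.5, T = 1.8, O = 1.8, F = 0.6)),
                   scalp_topography("central")),
    component_spec("N400", 480, 80,
                   amp(-5.0, c(S = -3.0, T = -1.5, O = -1.5, F = -4.0)),
                   scalp_topography("centroparietal")),
    component_spec("P200f", 220, 35,
                   amp(0.0, c(F = 1.5, T = 0.6, O = 0.6)),
                   scalp_topography("frontal_right"))
  )
}
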