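# Synthetic expansion-microscopy measurements: axoneme width lists and
# two-channel intensity profiles with a polyglutamylation gap.

#' Simulate U-ExM width measurements and intensity profiles
#'
#' Widths are drawn from Normal(ef x reference, noise_sigma), emulating
#' measured expanded axoneme widths. The intensity profile carries two
#' channels on an expanded-scale position grid: `tubulin`, a single
#' rectangular pulse spanning basal body and axoneme, and `gt335`
#' (polyglutamylated tubulin), two rectangular pulses whose half-maximum
#' edges are separated by `gap` nm on the corrected (pre-expansion) scale.
#' The grid step is defined on the corrected scale so that pulse edges fall
#' exactly on grid points; a noise-free gap is therefore recovered exactly
#' by [gap_length()].
#'
#' @param n_widths number of width measurements (default 30).
#' @param ef expansion factor (default 4.422).
#' @param reference reference axoneme width, nm (default 250).
#' @param noise_sigma width noise SD, nm (expanded scale).
#' @param gap GT335 gap on the corrected scale, nm (default 274, the
#'   transition-zone length).
#' @param pulse_len length of each GT335 pulse, corrected nm.
#' @param sample_step profile grid step, corrected nm (default 0.5).
#' @param intensity_noise additive intensity noise SD as a fraction of the
#'   pulse height.
#' @param seed integer RNG seed.
#' @return list with `widths` (numeric, expanded nm), `profile`
#'   (data.frame `position` in expanded nm, `tubulin`, `gt335`), `ef`, and
#'   `truth` (the generating parameters).
#' @export
gen_uexm <- function(n_widths = 30, ef = 4.422, reference = 250,
                     noise_sigma = 0, gap = 274, pulse_len = 200,
                     sample_step = 0.5, intensity_noise = 0, seed = 1) {
  if (ef <= 0) stopf("gen_uexm: ef must be > 0")
  if (reference <= 0) stopf("gen_uexm: reference must be > 0")
  if (sample_step <= 0) stopf("gen_uexm: sample_step must be > 0")
  snap <- function(x) round(x / sample_step) * sample_step
  margin <- 25
  a1 <- snap(margin)
  b1 <- snap(a1 + pulse_len)
  a2 <- snap(b1 + gap)
  b2 <- snap(a2 + pulse_len)
  pos_corr <- seq(0, b2 + margin, by = sample_step)
  gt <- as.numeric((pos_corr >= a1 & pos_corr <= b1) |
                     (pos_corr >= a2 & pos_corr <= b2))
  tub <- as.numeric(pos_corr >= a1 & pos_corr <= b2)
  with_seed(seed, {
    widths <- stats::rnorm(n_widths, ef * reference, noise_sigma)
    if (intensity_noise > 0) {
      gt <- pmax(0, gt + stats::rnorm(length(gt), 0, intensity_noise))
      tub <- pmax(0, tub + stats::rnorm(length(tub), 0, intensity_noise))
    }
    list(widths = widths,
         profile = data.frame(position = pos_corr * ef, tubulin = tub, gt335 = gt),
         ef = ef,
         truth = list(gap = a2 - b1, reference = reference,
                      pulse_edges = c(a1, b1, a2, b2) * ef,
                      sample_step = sample_step))
  })
}
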