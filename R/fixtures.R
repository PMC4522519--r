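#' Committed reference models
#'
#' Three fully specified parameter sets used throughout the tests and
#' examples; their behaviour (hysteresis gap, classical embeddability,
#' Leggett--Garg violation) is asserted by the acceptance suite.
#'
#' * `"hysteresis"` -- an unsharp measurement (mu = (-pi/8, pi/8)) of an
#'   agent with an L-leaning pre-recognition sensation state and moderate
#'   angle-to-rotation coupling (b = 0.75): the clockwise and
#'   counterclockwise presentation orders produce marginal curves that differ
#'   by more than 0.1 at some angle, and a random order gives a third
#'   distinct curve -- the qualitative analogue of the experimentally
#'   observed order dependence.
#' * `"classical"` -- diagonal (phase-only) sensation dynamics with a
#'   basis-controlled interaction and per-step perception reset: everything
#'   commutes with the outcome basis, the statistics are a mixture of
#'   conditionally i.i.d. classical processes, and all contexts embed in one
#'   Kolmogorov space (K <= 1).
#' * `"contextual"` -- angle-independent rotation of the sensation plane by
#'   pi/6 between sharp measurements (controlled rotation mu = (-pi/4, pi/4)
#'   on the neutral perception state, perception reset each step): the
#'   textbook temporal-correlation setting, with two-time correlators
#'   cos(pi/3) for adjacent and cos(2*pi/3) for outer pairs, hence
#'   K = 1.5 > 1 and no classical joint distribution.
#'
#' @param name which reference model.
#' @return A [schroeder_model()].
#' @examples
#' fixture_model("contextual")
#' @export
fixture_model <- function(name = c("hysteresis", "classical", "contextual")) {
  name <- match.arg(name)
  switch(name,
    hysteresis = schroeder_model(
      family = sensation_family(a = 0, b = 0.75),
      interaction = controlled_rotation(c(-pi / 8, pi / 8)),
      rho0 = pure_to_density(c(1, 0)),
      reset_sigma = FALSE),
    classical = schroeder_model(
      family = diagonal_phase_family(alpha = 1),
      interaction = controlled_rotation(c(-pi / 8, pi / 8)),
      rho0 = qstate(diag(c(0.7, 0.3)) + 0i),
      reset_sigma = TRUE),
    contextual = schroeder_model(
      family = sensation_family(a = pi / 6, b = 0),
      interaction = controlled_rotation(c(-pi / 4, pi / 4)),
      rho0 = qstate(diag(2) / 2),
      reset_sigma = TRUE))
}
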