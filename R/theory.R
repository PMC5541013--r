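#' Effective one-MCS activation probability of a fully shared node
#'
#' For a node present in both layers (duplex, `q = 1`) with persistence
#' time `tau`, the chance that it is selected to activate at least once
#' during one Monte Carlo step — in either layer's sweep — is
#' \deqn{P_{act}(\tau) = \frac{b_1 + b_2}{\tau} - \frac{b_1 b_2}{\tau^2},}
#' obtained by summing the three activation scenarios of a step (layer 1
#' only, layer 2 only, both) and independent of which layer is swept
#' first. On its domain `tau >= 1 + min(b1, b2)` the expression is
#' strictly positive: the large-`tau` decay `~(b1 + b2)/tau` is what sets
#' the `b1 + b2` tail exponents of the coupled dynamics.
#'
#' @param tau persistence time(s), `>= 1 + min(b1, b2)`.
#' @param b1,b2 activation coefficients, `>= 1` in the model's regime
#'   (values below 1 are accepted for algebraic checks).
#' @return Probability value(s) in `(0, 1]`.
#' @export
#' @examples
#' effective_activation(2, 1, 1)  # 0.75
effective_activation <- function(tau, b1, b2) {
  if (any(tau < 1 + min(b1, b2)))
    stop("tau must be >= 1 + min(b1, b2)", call. = FALSE)
  (b1 + b2) / tau - b1 * b2 / tau^2
}

#' Plateau levels of the trapped configurations (complete graphs)
#'
#' In a trapped realization one layer (dominant) orders almost fully
#' while the other (dominated) keeps `~qN` common nodes in the opposite
#' state. Counting active links on a complete graph with `N (N - 1) / 2`
#' edges gives three plateau levels of the active-link density:
#' \describe{
#'   \item{rho_low}{dominant layer with a single dissenting common node:
#'     `(N - 1) / (N (N - 1) / 2) = 2 / N`.}
#'   \item{rho_up}{dominated layer with all `q (N - 1)` common nodes in
#'     the contrary state; exact finite-N value and its large-N limit
#'     `2 q (1 - q)`.}
#'   \item{rho_half}{the earlier plateau while layer dominance is still
#'     undecided and half of the common nodes hold each opinion; exact
#'     value and large-N limit `q (1 - q / 2)`.}
#' }
#'
#' @param N nodes per layer, `>= 2`.
#' @param q multiplexity in `(0, 1]`.
#' @return Named list `rho_low`, `rho_up_exact`, `rho_up_asym`,
#'   `rho_half_exact`, `rho_half_asym`.
#' @export
#' @examples
#' plateaus(1000, 0.2)
plateaus <- function(N, q) {
  if (!is.numeric(N) || N < 2) stop("N must be >= 2", call. = FALSE)
  if (!is.numeric(q) || any(q <= 0) || any(q > 1))
    stop("q must be in (0, 1]", call. = FALSE)
  half_edges <- N * (N - 1) / 2
  list(
    rho_low = 2 / N,
    rho_up_exact = q * (N - 1) * (N - q * (N - 1)) / half_edges,
    rho_up_asym = 2 * q * (1 - q),
    rho_half_exact = (q * N / 2) * (N - q * N / 2) / half_edges,
    rho_half_asym = q * (1 - q / 2)
  )
}

#' Predicted power-law tail exponent of the coarsening decay
#'
#' For endogenous (ageing) dynamics on complete graphs the active-link
#' density and the inter-event CCDF decay as power laws whose exponent is
#' set by the activation coefficients: `b` per layer for two uncoupled
#' layers (`q = 0`, the monolayer limit) and `b1 + b2` for the fully
#' shared duplex (`q = 1`), where every node attempts an update in both
#' layers each MCS. No closed-form prediction is available at
#' intermediate `q` or for RAU-only dynamics.
#'
#' @param rules a [rule_spec()].
#' @param q multiplexity.
#' @return List with `covered` (logical), `exponent` (per the prediction;
#'   a two-vector `c(b1, b2)` at `q = 0`, a scalar `b1 + b2` at `q = 1`,
#'   `NA` otherwise) and `note`.
#' @export
predicted_tail_exponent <- function(rules, q) {
  stopifnot(inherits(rules, "rule_spec"))
  if (rules$rule1 != "endogenous" && rules$rule2 != "endogenous")
    return(list(covered = FALSE, exponent = NA_real_,
                note = "RAU-only dynamics: no power-law prediction"))
  if (rules$rule1 != rules$rule2)
    return(list(covered = FALSE, exponent = NA_real_,
                note = "mixed update rules: no closed-form exponent"))
  if (q == 1)
    return(list(covered = TRUE, exponent = rules$b1 + rules$b2,
                note = "duplex complete graph: b1 + b2"))
  if (q == 0)
    return(list(covered = TRUE, exponent = c(rules$b1, rules$b2),
                note = "uncoupled complete-graph monolayers: b per layer"))
  list(covered = FALSE, exponent = NA_real_,
       note = "intermediate q: no closed-form exponent")
}
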