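#' Behavioral parameters of the social information integration model
#'
#' The model describes how an agent weights the mean `M` of received
#' log-estimates when revising: with probability `P0` the agent keeps the
#' personal estimate (`S = 0`), otherwise `S` is drawn from a Gaussian of
#' mean `m_g` and standard deviation `sigma_g`.  The mean sensitivity
#' follows a linear cusp in the distance `D = M - X_p`,
#' `<S> = alpha + beta_pm * |D - D0| + beta_prime * sigma`, with separate
#' slopes left (`beta_minus`) and right (`beta_plus`) of the cusp bottom
#' `D0`, and a similarity term in the dispersion `sigma` of the received
#' estimates (only when more than one estimate is shared).  `m_g` and
#' `sigma_g` are constants at `tau = 1` and linear functions of the
#' dispersion at `tau > 1`.
#'
#' Two reduced variants switch off single mechanisms: `"no_asymmetry"`
#' forces `D0 = 0` and a common slope `(beta_minus + beta_plus) / 2`;
#' `"no_similarity"` zeroes `beta_prime` and the dispersion slopes of
#' `m_g` and `sigma_g`.
#'
#' @param tau1 Named list of the single-estimate block: `m_g`, `sigma_g`,
#'   `D0`, `alpha`, `beta_minus`, `beta_plus`.
#' @param tau_gt1 Named list of the multi-estimate block: `D0`, `alpha`,
#'   `beta_minus`, `beta_plus`, `beta_prime`, `m_g_intercept`,
#'   `m_g_slope`, `sigma_g_intercept`, `sigma_g_slope`.
#' @param variant `"full"`, `"no_similarity"` or `"no_asymmetry"`.
#' @return A list of class `"influence_params"`.
#' @seealso [default_influence_params()], [apply_variant()]
#' @export
influence_params <- function(tau1, tau_gt1,
                             variant = c("full", "no_similarity", "no_asymmetry")) {
  variant <- match.arg(variant)
  need <- function(block, fields, name) {
    missing <- setdiff(fields, names(block))
    if (length(missing))
      stop_domain("missing ", name, " parameter(s): ", paste(missing, collapse = ", "))
    lapply(block[fields], as.numeric)
  }
  tau1 <- need(tau1, c("m_g", "sigma_g", "D0", "alpha", "beta_minus", "beta_plus"),
               "tau1")
  tau_gt1 <- need(tau_gt1, c("D0", "alpha", "beta_minus", "beta_plus", "beta_prime",
                             "m_g_intercept", "m_g_slope",
                             "sigma_g_intercept", "sigma_g_slope"),
                  "tau_gt1")
  if (tau1$sigma_g < 0 || tau_gt1$sigma_g_intercept < 0)
    stop_domain("sigma_g must be non-negative")
  p <- structure(list(tau1 = tau1, tau_gt1 = tau_gt1, variant = "full"),
                 class = "influence_params")
  if (variant != "full") p <- apply_variant(p, variant)
  p
}

#' Reduce a parameter set to a model variant
#'
#' @param params An [influence_params()] object (full variant).
#' @param variant `"full"` (returned unchanged), `"no_similarity"` or
#'   `"no_asymmetry"`.
#' @return The transformed `influence_params` object with its `variant`
#'   field set.
#' @export
apply_variant <- function(params, variant = c("full", "no_similarity", "no_asymmetry")) {
  stopifnot(inherits(params, "influence_params"))
  variant <- match.arg(variant)
  if (variant == "no_similarity") {
    params$tau_gt1$beta_prime <- 0
    params$tau_gt1$m_g_slope <- 0
    params$tau_gt1$sigma_g_slope <- 0
  } else if (variant == "no_asymmetry") {
    for (block in c("tau1", "tau_gt1")) {
      b <- params[[block]]
      b$D0 <- 0
      b$beta_minus <- b$beta_plus <- (b$beta_minus + b$beta_plus) / 2
      params[[block]] <- b
    }
  }
  params$variant <- variant
  params
}

#' Demonstration parameter set
#'
#' A fit-for-demo parameter set with the qualitative features observed in
#' estimation experiments: a cusp bottom below zero and a steeper right
#' slope (asymmetry, favoring social information above one's own
#' estimate), a negative similarity slope (disparate information is
#' followed less), `m_g` decreasing and `sigma_g` increasing with the
#' dispersion of the received estimates, and mean sensitivities in the
#' herding range.  Model parameters are inputs to the simulator; sets
#' estimated from data come out of [fit_influence_params()].
#'
#' @param variant Model variant passed to [influence_params()].
#' @return An `influence_params` object.
#' @export
default_influence_params <- function(variant = "full") {
  influence_params(
    tau1 = list(m_g = 0.55, sigma_g = 0.40, D0 = -0.25, alpha = 0.30,
                beta_minus = 0.05, beta_plus = 0.12),
    tau_gt1 = list(D0 = -0.25, alpha = 0.35, beta_minus = 0.05, beta_plus = 0.12,
                   beta_prime = -0.25,
                   m_g_intercept = 0.65, m_g_slope = -0.20,
                   sigma_g_intercept = 0.30, sigma_g_slope = 0.20),
    variant = variant
  )
}

# Resolve params into one set per treatment (a single set is recycled).
params_by_treatment <- function(params, treatments) {
  if (inherits(params, "influence_params"))
    return(setNames(rep(list(params), length(treatments)), treatments))
  if (!all(treatments %in% names(params)))
    stop_domain("params must be an influence_params object or a named list ",
                "covering treatments: ", paste(treatments, collapse = ", "))
  params[treatments]
}
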