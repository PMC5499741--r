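#' Kinetic parameters of the promoter-switching / mRNA-folding model
#'
#' Bundles the rate constants of the stochastic gene-expression model: a
#' two-state promoter (off state D0, on state D1), transcription of mRNA
#' whose 5'UTR interconverts between an unfolded, translatable state
#' (\code{R_u}) and a folded, scanning-blocked state (\code{R_f}), translation
#' from unfolded mRNA only (by default), and first-order degradation of mRNA
#' and protein.
#'
#' Units are arbitrary reciprocal time; only rate ratios matter for
#' stationary coefficients of variation.
#'
#' @param k_on promoter activation rate (D0 -> D1).
#' @param k_off promoter inactivation rate (D1 -> D0). \code{k_off = 0}
#'   gives a constitutive promoter.
#' @param v_tx transcription rate from the active promoter (mRNA per time).
#' @param k_fold mRNA folding rate (R_u -> R_f). \code{k_fold = 0} reduces
#'   the model to the standard telegraph + translation model.
#' @param k_unfold mRNA unfolding rate (R_f -> R_u).
#' @param k_tl translation rate per unfolded mRNA (protein per time).
#' @param k_tl_fold translation rate per folded mRNA; defaults to 0
#'   (structure fully blocks scanning). A reduced-rate variant can be
#'   expressed by setting this to a positive value.
#' @param gamma_R mRNA degradation rate, applied identically to folded and
#'   unfolded mRNA (stem-loops do not measurably change mRNA abundance).
#' @param gamma_P protein degradation rate.
#' @param birth_state folding state of nascent mRNA: \code{"equilibrium"}
#'   (default; each transcript is born folded with probability
#'   \code{k_fold/(k_fold+k_unfold)}, the hairpin's thermodynamic
#'   equilibrium, reflecting fast co-transcriptional folding),
#'   \code{"unfolded"}, or \code{"folded"}.
#'
#' @return An object of class \code{"model_params"} (a named list).
#' @examples
#' p <- model_params(k_on = 1, k_off = 1, v_tx = 20, gamma_R = 1)
#' telegraph_moments(p)
#' @export
model_params <- function(k_on = 1, k_off = 0, v_tx = 10,
                         k_fold = 0, k_unfold = 0,
                         k_tl = 0, k_tl_fold = 0,
                         gamma_R = 1, gamma_P = 1,
                         birth_state = c("equilibrium", "unfolded", "folded")) {
  birth_state <- match.arg(birth_state)
  p <- list(k_on = k_on, k_off = k_off, v_tx = v_tx,
            k_fold = k_fold, k_unfold = k_unfold,
            k_tl = k_tl, k_tl_fold = k_tl_fold,
            gamma_R = gamma_R, gamma_P = gamma_P,
            birth_state = birth_state)
  rates <- unlist(p[rate_names()])
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be finite and >= 0", call. = FALSE)
  class(p) <- "model_params"
  p
}

rate_names <- function() {
  c("k_on", "k_off", "v_tx", "k_fold", "k_unfold",
    "k_tl", "k_tl_fold", "gamma_R", "gamma_P")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Promoter-switching / mRNA-folding model parameters\n")
  for (nm in rate_names())
    cat(sprintf("  %-10s %g\n", nm, x[[nm]]))
  cat(sprintf("  nascent mRNA folding state: %s\n", x$birth_state))
  invisible(x)
}

# probability that a nascent transcript is born unfolded
birth_unfolded_prob <- function(params) {
  switch(params$birth_state,
         unfolded = 1,
         folded = 0,
         equilibrium = {
           ks <- params$k_fold + params$k_unfold
           if (ks == 0) 1 else params$k_unfold / ks
         })
}

#' Stationary mRNA moments of the telegraph model (closed form)
#'
#' Analytic stationary mean, Fano factor and CV of mRNA copy number for the
#' two-state (telegraph) promoter model without mRNA folding:
#' \deqn{\langle R\rangle = \frac{v_{tx} k_{on}}{\gamma_R (k_{on}+k_{off})},
#' \quad F = 1 + \frac{v_{tx} k_{off}}{(k_{on}+k_{off})(k_{on}+k_{off}+\gamma_R)}.}
#' Serves as an independent oracle for the stochastic simulator.
#'
#' @param params a [model_params()] object with \code{k_fold = 0} and
#'   \code{gamma_R > 0}.
#' @return A list with \code{mean_R}, \code{fano_R} and \code{cv_R}.
#' @examples
#' telegraph_moments(model_params(k_on = 1, k_off = 1, v_tx = 20, gamma_R = 1))
#' @export
telegraph_moments <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$k_fold != 0)
    stop("telegraph oracle is only valid for k_fold = 0", call. = FALSE)
  if (params$gamma_R <= 0)
    stop("gamma_R must be > 0 for stationary moments", call. = FALSE)
  kon <- params$k_on; koff <- params$k_off
  v <- params$v_tx; g <- params$gamma_R
  if (kon + koff <= 0)
    stop("k_on + k_off must be > 0", call. = FALSE)
  mean_R <- v * kon / (g * (kon + koff))
  fano_R <- 1 + v * koff / ((kon + koff) * (kon + koff + g))
  list(mean_R = mean_R, fano_R = fano_R,
       cv_R = sqrt(fano_R / mean_R))
}

#' Stationary protein noise of the constitutive two-stage model (closed form)
#'
#' Analytic protein CV^2 for the constitutive (always-on promoter,
#' no-folding) two-stage birth-death model:
#' \deqn{CV_P^2 = \frac{1}{\langle P\rangle} +
#'   \frac{\gamma_P}{\gamma_R+\gamma_P}\,\frac{1}{\langle R\rangle}}
#' with \eqn{\langle R\rangle = v_{tx}/\gamma_R} and
#' \eqn{\langle P\rangle = k_{tl}\langle R\rangle/\gamma_P}.
#'
#' @param params a [model_params()] object with \code{k_off = 0},
#'   \code{k_fold = 0}, \code{gamma_R > 0} and \code{gamma_P > 0}.
#' @return A list with \code{mean_R}, \code{mean_P} and \code{cv2_P}.
#' @examples
#' two_stage_protein_cv2(model_params(k_off = 0, v_tx = 10, k_tl = 10,
#'                                    gamma_R = 1, gamma_P = 1))
#' @export
two_stage_protein_cv2 <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$k_off != 0 || params$k_fold != 0)
    stop("two-stage oracle requires a constitutive promoter (k_off = 0) ",
         "and no folding (k_fold = 0)", call. = FALSE)
  if (params$gamma_R <= 0 || params$gamma_P <= 0)
    stop("gamma_R and gamma_P must be > 0", call. = FALSE)
  mean_R <- params$v_tx / params$gamma_R
  mean_P <- params$k_tl * mean_R / params$gamma_P
  if (mean_P <= 0)
    stop("mean protein level is 0; check v_tx and k_tl", call. = FALSE)
  cv2 <- 1 / mean_P +
    (params$gamma_P / (params$gamma_R + params$gamma_P)) / mean_R
  list(mean_R = mean_R, mean_P = mean_P, cv2_P = cv2)
}
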