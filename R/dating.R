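#' Date a loss of selective constraint from branch-average omega
#'
#' Models the focal branch of duration `T` million years as two eras: a
#' constrained era evolving at `omega_constrained` followed by a neutral
#' era at omega = 1 after function was lost. The fitted branch-average
#' omega then mixes the two eras,
#' `omega_obs * T = omega_constrained * (T - t_loss) + 1 * t_loss`,
#' which solves to
#' `t_loss = T * (omega_obs - omega_constrained) / (1 - omega_constrained)`.
#' The result is clamped to `[0, T]`.
#'
#' @param omega_obs fitted omega on the focal branch; must be <= 1 (the
#'   two-era mixture cannot exceed neutrality).
#' @param omega_constrained omega of the constrained era, e.g. the average
#'   over background lineages; in `[0, 1)`.
#' @param duration_my branch duration `T` in million years (> 0).
#' @return time since loss of constraint, million years before present.
#' @examples
#' # a drifting green-opsin-like gene: branch omega 0.268 against a
#' # background average of 0.021, on a branch spanning at most 50 My
#' date_loss_of_function(0.26785, 0.021, 50)
#' @export
date_loss_of_function <- function(omega_obs, omega_constrained, duration_my) {
  if (duration_my <= 0) stop("duration_my must be > 0")
  if (omega_constrained < 0 || omega_constrained > 1)
    stop("omega_constrained must lie in [0, 1]")
  if (omega_constrained == 1)
    stop("omega_constrained = 1 is degenerate: no constraint to lose")
  if (omega_obs < 0) stop("omega_obs must be >= 0")
  if (omega_obs > 1)
    stop("omega_obs > 1: the constrained-to-neutral mixture cannot exceed ",
         "neutrality; a branch omega above 1 indicates positive selection, ",
         "not drift")
  if (omega_obs < omega_constrained) {
    warning("omega_obs below omega_constrained; returning 0 (no evidence ",
            "of relaxation)")
    return(0)
  }
  t_loss <- duration_my * (omega_obs - omega_constrained) /
    (1 - omega_constrained)
  min(max(t_loss, 0), duration_my)
}
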