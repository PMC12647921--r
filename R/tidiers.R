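# broom-style tidiers for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a robust bin-model fit
#'
#' @param x A `picdf_binfit`.
#' @param effects `"fixed"` for coefficient rows (default), `"emmeans"` for
#'   the estimated-marginal-mean grid, `"contrasts"` for Wald contrasts.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy picdf_binfit
#' @export
tidy.picdf_binfit <- function(x, effects = c("fixed", "emmeans", "contrasts"),
                              ...) {
  effects <- match.arg(effects)
  switch(effects,
         fixed = x$coefs,
         emmeans = tibble::as_tibble(x$emm),
         contrasts = tibble::as_tibble(x$contrasts))
}

#' @rdname tidy.picdf_binfit
#' @method glance picdf_binfit
#' @export
glance.picdf_binfit <- function(x, ...) {
  tibble::tibble(
    nobs = x$nobs,
    n_participants = x$n_participants,
    iterations = x$rlmm$iterations,
    converged = x$rlmm$converged,
    sigma = if (is.null(x$rlmm$fit)) 0 else stats::sigma(x$rlmm$fit),
    bin = as.character(x$bin %||% NA_character_)
  )
}

#' Tidy a delta-F association fit
#'
#' @param x A `picdf_assoc`.
#' @param effects `"slopes"` (default) for per-stratum slopes or `"fixed"`
#'   for raw coefficients.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy picdf_assoc
#' @export
tidy.picdf_assoc <- function(x, effects = c("slopes", "fixed"), ...) {
  effects <- match.arg(effects)
  if (effects == "slopes") x$slopes else x$coefs
}

#' @rdname tidy.picdf_assoc
#' @method glance picdf_assoc
#' @export
glance.picdf_assoc <- function(x, ...) {
  tibble::tibble(
    measure = x$measure,
    r2m = x$r2m,
    r2c = x$r2c,
    nobs = x$nobs,
    n_participants = x$n_participants,
    converged = x$rlmm$converged
  )
}
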