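#' Modulating effects of a substrate on the proliferation rate
#'
#' A modulating effect is a multiplicative factor applied to the logistic
#' proliferation term, describing how a substrate concentration influences
#' growth: constant (`zero_order`), proportional (`first_order`), or
#' saturating Michaelis-Menten with positive (`mmk_positive`) or negative
#' (`mmk_negative`) feedback. MMK kinds carry a half-saturation constant
#' `K` (mol m^-3).
#'
#' @param kind One of `"zero_order"`, `"first_order"`, `"mmk_positive"`,
#'   `"mmk_negative"`.
#' @param K Half-saturation constant; required (and `> 0`) for MMK kinds,
#'   forbidden otherwise.
#' @return An object of class `modulating_effect`.
#' @examples
#' modulating_factor(modulating_effect("mmk_positive", K = 2), c = 2)  # 0.5
#' @export
modulating_effect <- function(kind, K = NULL) {
  kind <- match.arg(kind, c("zero_order", "first_order",
                            "mmk_positive", "mmk_negative"))
  if (kind %in% c("mmk_positive", "mmk_negative")) {
    if (is.null(K) || !is.finite(K) || K <= 0)
      stop("MMK effects require a finite positive half-saturation constant K",
           call. = FALSE)
  } else {
    if (!is.null(K))
      stop("kind '", kind, "' carries no K", call. = FALSE)
    K <- NA_real_
  }
  structure(list(kind = kind, K = as.numeric(K)), class = "modulating_effect")
}

#' @export
print.modulating_effect <- function(x, ...) {
  if (is.na(x$K)) cat("<modulating_effect>", x$kind, "\n")
  else cat("<modulating_effect>", x$kind, " K =", format(x$K), "\n")
  invisible(x)
}

#' Evaluate a modulating effect at a concentration
#'
#' Returns 1 for zero-order, `c` for first-order, `c/(c+K)` for positive
#' MMK and `K/(c+K)` for negative MMK. MMK outputs always lie in `[0, 1]`.
#'
#' @param effect A [modulating_effect()].
#' @param c Non-negative concentration(s) (mol m^-3); vectorised.
#' @return Numeric vector of factors.
#' @export
modulating_factor <- function(effect, c) {
  stopifnot(inherits(effect, "modulating_effect"))
  if (any(!is.finite(c)) || any(c < 0))
    stop("concentration must be finite and non-negative", call. = FALSE)
  switch(effect$kind,
    zero_order   = rep(1, length(c)),
    first_order  = c,
    mmk_positive = c / (c + effect$K),
    mmk_negative = effect$K / (c + effect$K)
  )
}

#' Per-cell reaction rate for a substrate
#'
#' The per-cell reaction term R(c) under the chosen kinetics; the volumetric
#' rate is `n * R(c)`. Kinetics: `zero` gives `V`; `first` gives `V*c`;
#' `michaelis_menten` gives `V*c/(c + cbar)`; `competitive_inhibition`
#' additionally multiplies by `cbar_inh/(c_inh + cbar_inh)`.
#'
#' @param kinetics One of `"zero"`, `"first"`, `"michaelis_menten"`,
#'   `"competitive_inhibition"`.
#' @param V Rate constant.
#' @param c Substrate concentration (>= 0).
#' @param cbar Half-saturation constant (> 0 for MMK/competitive forms).
#' @param c_inhibitor Inhibitor concentration (competitive form only).
#' @param cbar_inhibition Inhibition constant (competitive form only).
#' @return Numeric reaction rate.
#' @export
reaction_rate <- function(kinetics, V, c, cbar = NULL,
                          c_inhibitor = 0, cbar_inhibition = NULL) {
  kinetics <- match.arg(kinetics, c("zero", "first", "michaelis_menten",
                                    "competitive_inhibition"))
  if (any(c < 0)) stop("concentration must be non-negative", call. = FALSE)
  needs_cbar <- kinetics %in% c("michaelis_menten", "competitive_inhibition")
  if (needs_cbar && (is.null(cbar) || any(cbar <= 0)))
    stop("kinetics '", kinetics, "' requires cbar > 0", call. = FALSE)
  switch(kinetics,
    zero = rep(V, length(c)),
    first = V * c,
    michaelis_menten = V * c / (c + cbar),
    competitive_inhibition = {
      if (is.null(cbar_inhibition) || any(cbar_inhibition <= 0))
        stop("competitive inhibition requires cbar_inhibition > 0",
             call. = FALSE)
      V * c / (c + cbar) * cbar_inhibition / (c_inhibitor + cbar_inhibition)
    }
  )
}
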