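#' Candidate growth models
#'
#' A candidate model assigns one modulating-effect kind to each substrate:
#' oxygen and glucose may be zero-order, first-order or saturating MMK with
#' positive feedback; lactate may be zero-order, first-order or MMK with
#' negative feedback (lactate inhibits growth). The full family therefore
#' contains 3 x 3 x 3 = 27 members.
#'
#' Models are named by which substrates carry an MMK effect ("Oxy", "Glu",
#' "Lac" concatenated; "Base" if none), with a suffix listing any
#' first-order substrates, e.g. `OxyGluLac` (all MMK) or `Oxy_fo.gl`
#' (oxygen MMK, glucose and lactate first-order). This keeps the 27 names
#' unique while matching the conventional labels for the all-MMK subsets.
#'
#' @param f_oxygen,f_glucose,f_lactate Effect kinds (character) for each
#'   substrate.
#' @return An object of class `candidate_model` with elements
#'   `kinds` (named character vector) and `name`.
#' @export
candidate_model <- function(f_oxygen, f_glucose, f_lactate) {
  f_oxygen  <- match.arg(f_oxygen,  c("zero_order", "first_order", "mmk_positive"))
  f_glucose <- match.arg(f_glucose, c("zero_order", "first_order", "mmk_positive"))
  f_lactate <- match.arg(f_lactate, c("zero_order", "first_order", "mmk_negative"))
  kinds <- c(oxygen = f_oxygen, glucose = f_glucose, lactate = f_lactate)
  structure(list(kinds = kinds, name = .candidate_name(kinds)),
            class = "candidate_model")
}

.candidate_name <- function(kinds) {
  mmk <- c("Oxy", "Glu", "Lac")[startsWith(kinds, "mmk")]
  fo <- c("o", "g", "l")[kinds == "first_order"]
  base <- if (length(mmk)) paste(mmk, collapse = "") else "Base"
  if (length(fo)) paste0(base, "_fo.", paste(fo, collapse = "")) else base
}

#' @export
print.candidate_model <- function(x, ...) {
  cat("<candidate_model>", x$name, ":",
      paste(names(x$kinds), x$kinds, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Integer effect codes used by the compiled solver
#' @noRd
.model_codes <- function(model) {
  code <- function(k) switch(k, zero_order = 0L, first_order = 1L, 2L)
  vapply(model$kinds, code, integer(1))
}

#' Enumerate the full candidate-model family
#'
#' Returns all combinations of permitted effect kinds in deterministic
#' lexicographic order (oxygen varying slowest, then glucose, then lactate),
#' optionally restricted per substrate.
#'
#' @param oxygen,glucose,lactate Character vectors of permitted kinds for
#'   each substrate (defaults: all three permitted kinds).
#' @return A list of [candidate_model()] objects (length 27 by default).
#' @export
enumerate_candidates <- function(
    oxygen  = c("zero_order", "first_order", "mmk_positive"),
    glucose = c("zero_order", "first_order", "mmk_positive"),
    lactate = c("zero_order", "first_order", "mmk_negative")) {
  grid <- expand.grid(f_lactate = lactate, f_glucose = glucose,
                      f_oxygen = oxygen, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies the first column fastest; ordering above makes the
  # output lexicographic in (oxygen, glucose, lactate)
  lapply(seq_len(nrow(grid)), function(i)
    candidate_model(grid$f_oxygen[i], grid$f_glucose[i], grid$f_lactate[i]))
}

#' Structural substrate dependence of the cell-population equation
#'
#' The population depends on a substrate either directly (its modulating
#' term is not zero-order) or indirectly through lactate: when lactate
#' modulates growth, oxygen reaches the population through the oxidative
#' lactate sink (requires `Vo > 0`) and glucose through glycolytic lactate
#' production (requires `Vg > 0`; `Vg` is a calibrated parameter, assumed
#' positive).
#'
#' @param model A [candidate_model()].
#' @param consts A [fixed_constants()] (only `Vo` matters here).
#' @return Named logical vector `c(oxygen = , glucose = )`.
#' @export
substrate_dependence <- function(model, consts = fixed_constants()) {
  k <- model$kinds
  lac_active <- k[["lactate"]] != "zero_order"
  c(oxygen  = k[["oxygen"]]  != "zero_order" || (lac_active && consts$Vo > 0),
    glucose = k[["glucose"]] != "zero_order" || lac_active)
}

#' Filter candidates by required substrate dependence
#'
#' Retains the models whose population dynamics depend on every substrate
#' in `required`. With the default constants and
#' `required = c("oxygen", "glucose")` applied to the full family of 27,
#' exactly 22 models are retained: the 5 discarded ones have a zero-order
#' lactate effect combined with a zero-order oxygen or glucose effect.
#'
#' @param models List of [candidate_model()] objects.
#' @param required Character subset of `c("oxygen", "glucose")`.
#' @param consts A [fixed_constants()].
#' @return The retained sub-list, in the original order.
#' @export
filter_candidates <- function(models, required = c("oxygen", "glucose"),
                              consts = fixed_constants()) {
  stopifnot(all(required %in% c("oxygen", "glucose")))
  keep <- vapply(models, function(m)
    all(substrate_dependence(m, consts)[required]), logical(1))
  models[keep]
}

#' Nested-limit relationship between two candidate models
#'
#' Reports whether `model_b` arises from `model_a` as a limit of MMK
#' half-saturation constants: a negative-feedback MMK term tends to
#' zero-order as `K -> Inf`, and a positive-feedback MMK term tends to
#' zero-order as `K -> 0` (after absorbing nothing: c/(c+K) -> 1). Limits
#' can only remove MMK structure, never add it or alter non-MMK terms.
#'
#' @param model_a,model_b [candidate_model()] objects.
#' @return A named character vector mapping substrates to limits
#'   (`"K -> Inf"` / `"K -> 0"`), empty if the models are identical, or
#'   `NULL` if `model_b` is not a limit of `model_a`.
#' @export
nested_limit_check <- function(model_a, model_b) {
  ka <- model_a$kinds; kb <- model_b$kinds
  lim <- character(0)
  for (s in names(ka)) {
    if (ka[[s]] == kb[[s]]) next
    if (ka[[s]] == "mmk_negative" && kb[[s]] == "zero_order")
      lim[s] <- "K -> Inf"
    else if (ka[[s]] == "mmk_positive" && kb[[s]] == "zero_order")
      lim[s] <- "K -> 0"
    else
      return(NULL)
  }
  lim
}
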