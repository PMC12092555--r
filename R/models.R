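#' Specify one member of the model ensemble
#'
#' Each ensemble member is a combination of three binary structural choices:
#' whether a mean difference is present (`effect`), whether the group
#' variances may differ (`variances`), and whether the observational
#' distribution is normal or Student-t (`likelihood`). A null effect fixes
#' \eqn{\delta = 0}; equal variances fix \eqn{\rho = 0.5}; a normal
#' likelihood fixes \eqn{\nu = \infty}.
#'
#' @param effect `"null"` or `"alternative"`.
#' @param variances `"equal"` or `"unequal"`.
#' @param likelihood `"normal"` or `"t"`.
#' @return An object of class `mbt_model_spec`.
#' @examples
#' model_spec("alternative", "unequal", "t")
#' @export
model_spec <- function(effect = c("null", "alternative"),
                       variances = c("equal", "unequal"),
                       likelihood = c("normal", "t")) {
  out <- list(effect = match.arg(effect),
              variances = match.arg(variances),
              likelihood = match.arg(likelihood))
  out$label <- spec_label(out)
  structure(out, class = "mbt_model_spec")
}

spec_label <- function(spec) {
  paste0(if (spec$effect == "null") "H0" else "H1",
         if (spec$variances == "unequal") ".uvar" else ".evar",
         if (spec$likelihood == "t") ".t" else ".norm")
}

#' @export
print.mbt_model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s>  effect=%s, variances=%s, likelihood=%s\n",
              x$label, x$effect, x$variances, x$likelihood))
  invisible(x)
}

#' @export
format.mbt_model_spec <- function(x, ...) x$label

#' Enumerate the models of a named ensemble
#'
#' * `"student"`: the equal-variance normal pair (null vs. alternative);
#' * `"welch"`: the unequal-variance normal pair;
#' * `"mb4"`: all four normal-likelihood models;
#' * `"romb8"`: the full 2 x 2 x 2 ensemble including t-likelihood models.
#'
#' @param ensemble Ensemble name.
#' @return A list of [model_spec()] objects, named by their labels.
#' @examples
#' names(model_grid("romb8"))
#' @export
model_grid <- function(ensemble = c("romb8", "mb4", "student", "welch")) {
  ensemble <- match.arg(ensemble)
  grid <- switch(ensemble,
    student = expand.grid(effect = c("null", "alternative"),
                          variances = "equal", likelihood = "normal",
                          stringsAsFactors = FALSE),
    welch = expand.grid(effect = c("null", "alternative"),
                        variances = "unequal", likelihood = "normal",
                        stringsAsFactors = FALSE),
    mb4 = expand.grid(effect = c("null", "alternative"),
                      variances = c("equal", "unequal"), likelihood = "normal",
                      stringsAsFactors = FALSE),
    romb8 = expand.grid(effect = c("null", "alternative"),
                        variances = c("equal", "unequal"),
                        likelihood = c("normal", "t"),
                        stringsAsFactors = FALSE)
  )
  specs <- purrr::pmap(grid, model_spec)
  names(specs) <- purrr::map_chr(specs, "label")
  specs
}

# free parameters of a spec, in canonical order
free_params <- function(spec) {
  c("mu", "sigma",
    if (spec$effect == "alternative") "delta",
    if (spec$variances == "unequal") "rho",
    if (spec$likelihood == "t") "nu")
}

# the set indicators used by the three inclusion Bayes factors
indicator_effect <- function(specs) {
  purrr::map_lgl(specs, ~ .x$effect == "alternative")
}
indicator_variances <- function(specs) {
  purrr::map_lgl(specs, ~ .x$variances == "unequal")
}
indicator_outliers <- function(specs) {
  purrr::map_lgl(specs, ~ .x$likelihood == "t")
}
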