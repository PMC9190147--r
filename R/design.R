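#' Build outcome and design matrices for the mixture model
#'
#' Converts a data frame plus a model formula into the pieces the likelihood
#' works with: the count outcome `y`, the marginal-mean design matrix `X`
#' (intercept first, treatment coding against each factor's first level), and
#' the component-1 design matrix `Z`. By default the two parts share the same
#' covariates (`Z = X`); a distinct `component_formula` (right-hand side only)
#' overrides `Z`.
#'
#' @param data A data frame with one row per subject.
#' @param formula Model formula, e.g. `anc_visits ~ residence + wealth_index`.
#'   A right-hand-side-only formula is allowed when no outcome is present
#'   (design for simulation).
#' @param component_formula Optional one-sided formula for the component-1
#'   mean.
#' @return A list of class `mpp_design`: `y` (or `NULL`), `X`, `Z`, `terms`,
#'   `xlevels`, `assign` (per-column term index of `X`).
#' @export
mpp_design <- function(data, formula, component_formula = NULL) {
  data <- as.data.frame(data)
  if (anyNA(data[all.vars(formula)])) {
    stop("`data` contains missing values in model variables; ",
         "apply complete-case filtering first (see `read_anc_data()`).",
         call. = FALSE)
  }
  mf <- stats::model.frame(formula, data)
  tt <- attr(mf, "terms")
  X <- stats::model.matrix(tt, mf)
  y <- if (attr(tt, "response") > 0) stats::model.response(mf) else NULL
  if (!is.null(y)) check_counts(y)
  if (is.null(component_formula)) {
    Z <- X
    z_terms <- tt
  } else {
    mfz <- stats::model.frame(component_formula, data)
    z_terms <- attr(mfz, "terms")
    Z <- stats::model.matrix(z_terms, mfz)
  }
  structure(
    list(
      y = y, X = X, Z = Z, terms = tt,
      xlevels = stats::.getXlevels(tt, mf),
      assign = attr(X, "assign")
    ),
    class = "mpp_design"
  )
}
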