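#' Inference configuration
#'
#' Collects the tunable parameters of the flow model. Distances are in the
#' native units of the coordinate table (Visium-style inputs are already
#' metric); expression values are used as given, with library-size
#' normalization recommended upstream.
#'
#' @param d_cutoff Distance cutoff (same units as the coordinates). A directed
#'   edge i -> j exists only when the Euclidean distance is strictly below
#'   this value.
#' @param lambda_affinity Weight of the affinity penalty in the edge cost
#'   `c = d/d_cutoff + lambda * (1 - abar)`. Nonnegative.
#' @param kappa_upper Proportionality constant for upper bounds
#'   `u = kappa * combine(E_R, S_L)`. Positive.
#' @param epsilon_lower Lower bound as a fraction of the upper bound on edges
#'   with at least one expressed prior-supported binder. Must be in [0, 1) so
#'   that lower <= upper always holds.
#' @param expr_threshold Expression threshold tau: a gene counts as expressed
#'   in a cell when its value is strictly greater than tau. Applied globally.
#' @param bound_combiner How receptor abundance `E_R` (target cell) and
#'   aggregate expressed-binder availability `S_L` (source cell) combine into
#'   the upper bound: `"min"` (capacity limited by the scarcer resource,
#'   default) or `"product"`.
#' @param quantum Integer flow units per unit of bound scale for the exact
#'   integral solver; larger values reduce quantization error.
#'
#' @return A list of class `flow_config`.
#' @export
flow_config <- function(d_cutoff,
                        lambda_affinity = 1,
                        kappa_upper = 1,
                        epsilon_lower = 0.05,
                        expr_threshold = 0,
                        bound_combiner = c("min", "product"),
                        quantum = 1000L) {
  bound_combiner <- match.arg(bound_combiner)
  stopifnot(is.numeric(d_cutoff), length(d_cutoff) == 1, d_cutoff > 0,
            is.numeric(lambda_affinity), lambda_affinity >= 0,
            is.numeric(kappa_upper), kappa_upper > 0,
            is.numeric(epsilon_lower), epsilon_lower >= 0, epsilon_lower < 1,
            is.numeric(expr_threshold), expr_threshold >= 0,
            is.numeric(quantum), quantum >= 1, quantum == as.integer(quantum))
  structure(list(d_cutoff = d_cutoff,
                 lambda_affinity = lambda_affinity,
                 kappa_upper = kappa_upper,
                 epsilon_lower = epsilon_lower,
                 expr_threshold = expr_threshold,
                 bound_combiner = bound_combiner,
                 quantum = as.integer(quantum)),
            class = "flow_config")
}

#' @exportS3Method base::print
print.flow_config <- function(x, ...) {
  cat("<flow_config>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
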