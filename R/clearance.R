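# Clearance-fold accounting across downstream unit operations.
#
# The fold for one step is the ratio of impurity-to-protein mass ratios
# across it; expressing clearance on the impurity/protein basis makes the
# number invariant to dilution or concentration of the pool. Non-detects are
# substituted with the assay LOD before the ratio is formed, which makes the
# resulting fold a lower bound on the true clearance.

#' Clearance fold across one unit operation
#'
#' \deqn{fold = \frac{C^{PRI}_{in} / C^{prot}_{in}}{C^{PRI}_{out} / C^{prot}_{out}}}
#'
#' @param m A [clearance_measurement()].
#' @return A `clearance_result`: list with `step_name`, `fold` (> 0) and
#'   `is_lower_bound` (mirrors the LOD substitution flag).
#' @examples
#' m <- clearance_measurement("protein A", 100, 5, 0.1, 5, final_is_lod = TRUE)
#' clearance_fold(m)  # 1000-fold, lower bound
#' @export
clearance_fold <- function(m) {
  stopifnot(inherits(m, "clearance_measurement"))
  fold <- (m$initial_pri / m$initial_protein) /
          (m$final_pri / m$final_protein)
  structure(list(step_name = m$step_name, fold = fold,
                 is_lower_bound = m$final_is_lod),
            class = "clearance_result")
}

#' @export
print.clearance_result <- function(x, ...) {
  cat(sprintf("<clearance_result> %s: %s%.4g-fold\n", x$step_name,
              if (x$is_lower_bound) ">" else "", x$fold))
  invisible(x)
}

#' Cumulative clearance across an ordered sequence of steps
#'
#' Fold factors compose multiplicatively (log-additively): the cumulative
#' clearance of a train of unit operations is the product of the per-step
#' folds. The lower-bound flag propagates by disjunction — if any step's fold
#' was limited by an assay LOD, the cumulative value is itself a lower bound.
#'
#' @param results Non-empty list of `clearance_result` objects (from
#'   [clearance_fold()]), in process order.
#' @return A `clearance_result` with `step_name` the `+`-joined step names.
#' @examples
#' steps <- list(
#'   structure(list(step_name = "proA", fold = 100, is_lower_bound = FALSE),
#'             class = "clearance_result"),
#'   structure(list(step_name = "cex", fold = 10, is_lower_bound = FALSE),
#'             class = "clearance_result"))
#' cumulative_clearance(steps)$fold  # 1000
#' @export
cumulative_clearance <- function(results) {
  if (length(results) == 0)
    stop("cumulative_clearance requires at least one step", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "clearance_result")))
  structure(
    list(step_name = paste(vapply(results, `[[`, character(1), "step_name"),
                           collapse = " + "),
         fold = prod(vapply(results, `[[`, numeric(1), "fold")),
         is_lower_bound = any(vapply(results, `[[`, logical(1),
                                     "is_lower_bound"))),
    class = "clearance_result")
}

#' Minimum platform clearance budget for a mAb downstream process
#'
#' The conservative clearance that a typical monoclonal-antibody downstream
#' process can be assumed to provide even before product-specific data exist:
#' 100-fold from Protein A capture, 10-fold from bind-and-elute cation
#' exchange, and 5-fold from diafiltration — 5,000-fold cumulatively. Each
#' step is individually overridable (e.g. drop a step the process lacks).
#'
#' @param protein_a,cex_bind_elute,diafiltration Per-step assumed minimum
#'   folds (> 0); set a step to `NULL` to remove it from the budget.
#' @return A `clearance_budget`: list with `steps` (named numeric vector) and
#'   `cumulative` fold.
#' @examples
#' platform_minimum_budget()$cumulative            # 5000
#' platform_minimum_budget(cex_bind_elute = NULL)$cumulative  # 500
#' @export
platform_minimum_budget <- function(protein_a = 100, cex_bind_elute = 10,
                                    diafiltration = 5) {
  steps <- c(protein_a = if (!is.null(protein_a)) as.numeric(protein_a),
             cex_bind_elute = if (!is.null(cex_bind_elute))
               as.numeric(cex_bind_elute),
             diafiltration = if (!is.null(diafiltration))
               as.numeric(diafiltration))
  if (length(steps) == 0)
    stop("clearance budget needs at least one step", call. = FALSE)
  if (any(!is.finite(steps)) || any(steps <= 0))
    stop("clearance budget overrides must be finite and > 0", call. = FALSE)
  structure(list(steps = steps, cumulative = prod(steps)),
            class = "clearance_budget")
}

#' @export
print.clearance_budget <- function(x, ...) {
  cat("<clearance_budget>\n")
  for (s in names(x$steps))
    cat(sprintf("  %-15s %g-fold\n", s, x$steps[[s]]))
  cat(sprintf("  cumulative      %g-fold\n", x$cumulative))
  invisible(x)
}
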