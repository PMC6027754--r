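# Modular degree-of-interest (DoI) engine.
#
# The DoI of an analysis is a weighted sum over five components:
# three binary user actions (FILTER: passes the active filter, HIGHLIGHT:
# lies on a traced path, SELECTED: explicitly chosen) and two continuous
# attributes in [0, 1] (TIME: recency of execution, DELTA: the normalized
# change metric of the containing layer). Component weights are
# user-adjustable but always renormalize to sum 1 over the enabled set, so
# the DoI itself stays in [0, 1]. The DoI value then selects the aggregation
# level of the analysis: low interest collapses into a layer, high interest
# expands down to individual workflow-instance nodes.

DOI_COMPONENTS <- c("FILTER", "HIGHLIGHT", "SELECTED", "TIME", "DELTA")

#' DoI component weights
#'
#' @param weights named numeric vector over (a subset of)
#'   `FILTER, HIGHLIGHT, SELECTED, TIME, DELTA`; defaults to equal weights
#'   0.2 on all five. Must be non-negative and sum to 1 over the enabled
#'   components (tolerance 1e-9).
#' @param enabled which components are active; weights of disabled components
#'   are 0.
#' @return object of class `doi_weights`.
#' @export
doi_weights <- function(weights = NULL, enabled = DOI_COMPONENTS) {
  enabled <- match.arg(enabled, DOI_COMPONENTS, several.ok = TRUE)
  if (length(enabled) == 0L) stopf("at least one DoI component must be enabled")
  w <- stats::setNames(numeric(length(DOI_COMPONENTS)), DOI_COMPONENTS)
  if (is.null(weights)) {
    w[enabled] <- 1 / length(enabled)
  } else {
    unknown <- setdiff(names(weights), DOI_COMPONENTS)
    if (length(unknown) > 0L) stopf("unknown DoI component(s): %s",
                                    paste(unknown, collapse = ", "))
    w[names(weights)] <- weights
    w[setdiff(DOI_COMPONENTS, enabled)] <- 0
  }
  out <- structure(list(w = w, enabled = enabled), class = "doi_weights")
  check_doi_weights(out)
  out
}

check_doi_weights <- function(weights) {
  w <- weights$w[weights$enabled]
  if (any(w < -1e-12)) stopf("DoI weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) {
    stopf("DoI weights over enabled components must sum to 1 (got %.12f)", sum(w))
  }
  invisible(weights)
}

#' @export
print.doi_weights <- function(x, ...) {
  cat("<doi_weights>\n")
  for (cmp in DOI_COMPONENTS) {
    cat(sprintf("  %-9s %.4f%s\n", cmp, x$w[[cmp]],
                if (cmp %in% x$enabled) "" else " (disabled)"))
  }
  invisible(x)
}

#' Set one component weight, renormalizing the rest
#'
#' The target component receives `new_value`; the remaining enabled weights
#' are scaled proportionally by `(1 - new_value) / (1 - old_value)` so the
#' total stays 1. When the target previously held all the weight, the
#' remainder is split equally among the other enabled components.
#'
#' @param weights a `doi_weights` object.
#' @param component one of the five component names (must be enabled).
#' @param new_value number in `[0, 1]`.
#' @return updated `doi_weights`.
#' @export
set_weight <- function(weights, component, new_value) {
  component <- match.arg(component, DOI_COMPONENTS)
  if (!(component %in% weights$enabled)) stopf("component %s is disabled", component)
  if (!is_scalar_number(new_value) || new_value < 0 || new_value > 1) {
    stopf("new_value must be in [0, 1]")
  }
  others <- setdiff(weights$enabled, component)
  old <- weights$w[[component]]
  w <- weights$w
  w[[component]] <- new_value
  if (length(others) > 0L) {
    if (old >= 1 - 1e-12) {
      w[others] <- (1 - new_value) / length(others)
    } else {
      w[others] <- w[others] * (1 - new_value) / (1 - old)
    }
  } else {
    w[[component]] <- 1
  }
  out <- structure(list(w = w, enabled = weights$enabled), class = "doi_weights")
  check_doi_weights(out)
  out
}

#' Enable or disable a DoI component
#'
#' Disabling redistributes the component's weight proportionally over the
#' remaining enabled components (equally when they all held zero weight);
#' enabling grants the component weight `1/n` (`n` = enabled count after the
#' toggle) and rescales the others by `1 - 1/n`. Disabling the last enabled
#' component is an error.
#'
#' @param weights a `doi_weights` object.
#' @param component component name.
#' @param on `TRUE` to enable, `FALSE` to disable.
#' @return updated `doi_weights`.
#' @export
toggle_component <- function(weights, component, on) {
  component <- match.arg(component, DOI_COMPONENTS)
  w <- weights$w
  enabled <- weights$enabled
  if (on) {
    if (component %in% enabled) return(weights)
    enabled <- DOI_COMPONENTS[DOI_COMPONENTS %in% c(enabled, component)]
    n <- length(enabled)
    w[setdiff(enabled, component)] <- w[setdiff(enabled, component)] * (1 - 1 / n)
    w[[component]] <- 1 / n
  } else {
    if (!(component %in% enabled)) return(weights)
    if (length(enabled) == 1L) stopf("cannot disable the last enabled DoI component")
    others <- setdiff(enabled, component)
    freed <- w[[component]]
    rest <- sum(w[others])
    if (rest <= 1e-12) {
      w[others] <- 1 / length(others)
    } else {
      w[others] <- w[others] * (rest + freed) / rest
    }
    w[[component]] <- 0
    enabled <- others
  }
  out <- structure(list(w = w, enabled = enabled), class = "doi_weights")
  check_doi_weights(out)
  out
}

#' DoI level thresholds
#'
#' Partition of the DoI range `[0, 1]` into aggregation levels, plus the
#' extraction threshold. Intervals are lower-inclusive:
#' `[0, t1) -> AL3`, `[t1, t2) -> AL2`, `[t2, t3) -> AL1`, `[t3, 1] -> AL0`.
#' An analysis whose DoI reaches `t_x` while its layer is still shown is
#' extracted (drawn as its own analysis node attached to the layer).
#'
#' @param t1,t2,t3 strictly increasing thresholds in `(0, 1)`.
#' @param t_x extraction threshold in `(0, 1)`.
#' @return object of class `doi_config`.
#' @export
doi_config <- function(t1 = 0.25, t2 = 0.5, t3 = 0.75, t_x = 0.25) {
  if (!(t1 > 0 && t1 < t2 && t2 < t3 && t3 < 1)) {
    stopf("thresholds must satisfy 0 < t1 < t2 < t3 < 1")
  }
  if (!is_scalar_number(t_x) || t_x <= 0 || t_x >= 1) stopf("t_x must be in (0, 1)")
  structure(list(t1 = t1, t2 = t2, t3 = t3, t_x = t_x), class = "doi_config")
}

#' Per-analysis DoI component values
#'
#' User-action components are 1 when the analysis id appears in the
#' corresponding flag set, else 0. `TIME` is execution time min-max
#' normalized over all analyses in the graph (0 for every analysis when all
#' times coincide; later runs score higher). `DELTA` is the normalized change
#' metric of the analysis's layer.
#'
#' @param graph a valid `provenance_graph`.
#' @param layers output of [compute_layer_deltas()].
#' @param flags list with character vectors `filter`, `highlight`, `selected`
#'   (analysis ids); missing entries are treated as empty.
#' @return numeric matrix, one row per analysis (rownames = analysis ids),
#'   columns `FILTER, HIGHLIGHT, SELECTED, TIME, DELTA`.
#' @export
compute_component_values <- function(graph, layers, flags = list()) {
  an <- graph$analyses
  layer_of <- attr(layers, "layer_of")
  norm <- stats::setNames(layers$delta_norm %||% rep(0, nrow(layers)), layers$id)
  v <- matrix(0, nrow = nrow(an), ncol = length(DOI_COMPONENTS),
              dimnames = list(an$id, DOI_COMPONENTS))
  if (nrow(an) == 0L) return(v)
  v[, "FILTER"] <- as.numeric(an$id %in% (flags$filter %||% character()))
  v[, "HIGHLIGHT"] <- as.numeric(an$id %in% (flags$highlight %||% character()))
  v[, "SELECTED"] <- as.numeric(an$id %in% (flags$selected %||% character()))
  t_min <- min(an$execution_time); t_max <- max(an$execution_time)
  v[, "TIME"] <- if (t_max == t_min) 0 else (an$execution_time - t_min) / (t_max - t_min)
  v[, "DELTA"] <- unname(norm[layer_of[an$id]])
  v
}

#' Combine component values into a DoI score
#'
#' `doi = sum over enabled components of w_i * v_i`; guaranteed to lie in
#' `[0, 1]` for valid weights and component values.
#'
#' @param vector numeric vector (or one-row slice of the matrix from
#'   [compute_component_values()]) named by component.
#' @param weights a valid `doi_weights`.
#' @return DoI value in `[0, 1]`.
#' @export
compute_doi <- function(vector, weights) {
  check_doi_weights(weights)
  en <- weights$enabled
  bad <- vector[en] < -1e-12 | vector[en] > 1 + 1e-12
  if (any(is.na(vector[en])) || any(bad)) {
    stopf("component values must lie in [0, 1]")
  }
  min(max(sum(weights$w[en] * vector[en]), 0), 1)
}

#' Map a DoI value to an aggregation level
#'
#' @param value DoI value(s) in `[0, 1]`.
#' @param config a [doi_config()].
#' @return character vector of levels (`"AL0"` most detailed ...
#'   `"AL3"` most aggregated).
#' @export
level_for_doi <- function(value, config = doi_config()) {
  if (any(is.na(value)) || any(value < 0) || any(value > 1)) {
    stopf("DoI value out of range [0, 1]")
  }
  ifelse(value < config$t1, "AL3",
         ifelse(value < config$t2, "AL2",
                ifelse(value < config$t3, "AL1", "AL0")))
}
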