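# Human <-> rat age translation from group-wise linear equations.

#' Construct a human-to-rat age translation model
#'
#' A translation model is a small lookup: group label ->
#' `(slope, intercept)` of the line `rat_pcd = slope * human_pcw +
#' intercept`, plus an optional map from brain region to group label. The
#' model is valid on the human foetal period (default `[4, 40]` pcw);
#' outside it translation still evaluates but warns about extrapolation.
#'
#' @param groups Data.frame with columns `label`, `slope` (> 0, pcd/pcw)
#'   and `intercept` (pcd).
#' @param region_map Optional named character vector region -> group label.
#' @param domain_pcw Length-2 valid human age interval in pcw.
#' @return A `translation_model`.
#' @seealso [default_translation_model()] for the shipped two-group model.
#' @export
translation_model <- function(groups, region_map = NULL,
                              domain_pcw = c(4, 40)) {
  stopifnot(all(c("label", "slope", "intercept") %in% names(groups)))
  if (any(groups$slope <= 0)) {
    abort("slopes must be positive (invertibility)", "devtrans_domain_error")
  }
  if (anyDuplicated(groups$label)) {
    abort("duplicate group labels", "devtrans_integrity_error")
  }
  if (!is.null(region_map)) {
    bad <- setdiff(unique(region_map), groups$label)
    if (length(bad) > 0) {
      abort(sprintf("region_map points at unknown group(s): %s",
                    paste(bad, collapse = ", ")),
            "devtrans_lookup_error")
    }
  }
  structure(
    list(groups = as.data.frame(groups)[, c("label", "slope", "intercept")],
         region_map = region_map, domain_pcw = domain_pcw),
    class = "translation_model"
  )
}

#' The shipped two-group human-to-rat translation model
#'
#' The final two-group model of the analysis, hard-coded as a data asset so
#' the package is a usable translator out of the box: the fast group `A2`
#' (spinal cord and brainstem), `rat_pcd = 1.258 * human_pcw + 6.832`, and
#' the slow group `B2` (DRG, cerebellum, hypothalamus and cortex),
#' `rat_pcd = 0.774 * human_pcw + 7.417`, with the published two-class
#' region assignment.
#'
#' @return A `translation_model`.
#' @examples
#' m <- default_translation_model()
#' translate_human_to_rat(m, 10, region = "isocortex")
#' @export
default_translation_model <- function() {
  groups <- data.frame(
    label = c("A2", "B2"),
    slope = c(1.258, 0.774),
    intercept = c(6.832, 7.417)
  )
  region_map <- c(
    "spinal cord" = "A2", "midbrain" = "A2", "thalamus" = "A2",
    "medulla/pons" = "A2", "retina" = "A2",
    "DRG" = "B2", "cerebellum" = "B2", "hypothalamus" = "B2",
    "subcortex" = "B2", "allocortex" = "B2", "isocortex" = "B2",
    "Other 1" = "A2", "Other 2" = "A2", "Other 3" = "A2",
    "Vomeronasal organ" = "B2", "Optic nerve" = "B2", "Skeleton" = "A2",
    "Other 4" = "A2", "Other 5" = "A2", "Other 6" = "A2",
    "Other 7" = "B2", "Other 8" = "B2", "Other 9" = "B2"
  )
  translation_model(groups, region_map)
}

.resolve_group <- function(model, region, group) {
  if (is.null(group) == is.null(region)) {
    abort("supply exactly one of region or group", "devtrans_argument_error")
  }
  if (!is.null(region)) {
    if (is.null(model$region_map) || !(region %in% names(model$region_map))) {
      abort(sprintf("unknown region '%s'", region), "devtrans_lookup_error")
    }
    group <- unname(model$region_map[region])
  }
  k <- match(group, model$groups$label)
  if (is.na(k)) {
    abort(sprintf("unknown group '%s'", group), "devtrans_lookup_error")
  }
  k
}

#' Translate a human foetal age to the rat scale
#'
#' @param model A [translation_model()].
#' @param pcw Human age(s) in postconceptional weeks.
#' @param region Brain region label (resolved through the model's region
#'   map), or
#' @param group Group label; supply exactly one of the two.
#' @return Rat age(s) in postconceptional days. Ages outside the model's
#'   valid human domain are extrapolated with a warning.
#' @export
translate_human_to_rat <- function(model, pcw, region = NULL, group = NULL) {
  k <- .resolve_group(model, region, group)
  if (any(pcw < model$domain_pcw[1] | pcw > model$domain_pcw[2])) {
    warning(sprintf("extrapolating outside the valid human domain [%g, %g] pcw",
                    model$domain_pcw[1], model$domain_pcw[2]))
  }
  model$groups$slope[k] * pcw + model$groups$intercept[k]
}

#' Translate a rat age to the human foetal scale
#'
#' Algebraic inverse of [translate_human_to_rat()]; the round trip is the
#' identity to floating precision.
#'
#' @param model A [translation_model()].
#' @param pcd Rat age(s) in postconceptional days.
#' @inheritParams translate_human_to_rat
#' @return Human age(s) in postconceptional weeks.
#' @export
translate_rat_to_human <- function(model, pcd, region = NULL, group = NULL) {
  k <- .resolve_group(model, region, group)
  slope <- model$groups$slope[k]
  if (abs(slope) < 1e-12) abort("zero slope", "devtrans_domain_error")
  pcw <- (pcd - model$groups$intercept[k]) / slope
  if (any(pcw < model$domain_pcw[1] | pcw > model$domain_pcw[2])) {
    warning(sprintf("extrapolating outside the valid human domain [%g, %g] pcw",
                    model$domain_pcw[1], model$domain_pcw[2]))
  }
  pcw
}

#' Least-squares slope through a fixed anchor point
#'
#' Regression constrained through the predefined developmental onset (by
#' default human 4 pcw, rat pcd 11 = E11):
#' `slope = sum((x - x0) (y - y0)) / sum((x - x0)^2)`. Used to compare
#' developmental paces while forcing every group through the same onset.
#'
#' @param events An [event_table()] subset with >= 1 event.
#' @param anchor Length-2 numeric `(x0 = pcw, y0 = pcd)`.
#' @return The constrained slope (pcd per pcw).
#' @export
anchored_slope <- function(events, anchor = c(pcw = 4, pcd = 11)) {
  if (nrow(events) < 1) abort("need >= 1 event", "devtrans_domain_error")
  dx <- events$human_pcw - anchor[[1]]
  if (sum(dx^2) <= 1e-12) {
    abort("degenerate design: all events at the anchor's x",
          "devtrans_degenerate_error")
  }
  sum(dx * (events$rat_pcd - anchor[[2]])) / sum(dx^2)
}

#' Build a translation model from a fitted mixture
#'
#' @param fit A labelled, converged `mixture_fit` (see [label_groups()]).
#' @param domain_pcw Valid human age interval.
#' @return A [translation_model()] whose region map is the fit's hard
#'   region assignment.
#' @export
translation_model_from_fit <- function(fit, domain_pcw = c(4, 40)) {
  if (is.null(fit$groups$label)) fit <- label_groups(fit)
  z <- hard_assignments(fit)
  translation_model(
    fit$groups[, c("label", "slope", "intercept")],
    region_map = stats::setNames(fit$groups$label[z], names(z)),
    domain_pcw = domain_pcw
  )
}

#' @export
print.translation_model <- function(x, ...) {
  cat("Human -> rat age translation model\n")
  for (k in seq_len(nrow(x$groups))) {
    cat(sprintf("  %s: rat_pcd = %.3f * human_pcw + %.3f\n",
                x$groups$label[k], x$groups$slope[k], x$groups$intercept[k]))
  }
  cat(sprintf("  valid human domain: [%g, %g] pcw; %d region(s) mapped\n",
              x$domain_pcw[1], x$domain_pcw[2], length(x$region_map)))
  invisible(x)
}
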