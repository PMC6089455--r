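# Decision framework for bidirectional MR evidence: classify the pattern of
# forward effect, heterogeneity, directional pleiotropy, reverse effect and
# Steiger directionality into one of three generative scenarios (or "null").

#' Classify bidirectional MR evidence
#'
#' Encodes a qualitative interpretation framework for a forward MR of a
#' binary trait's genetic liability on a quantitative phenotype together
#' with the reverse MR and a Steiger directionality test:
#'
#' * `"null"` - no forward effect (forward p >= `alpha_effect`);
#' * `"B"` (heterogeneous / confounded) - forward effect present but the
#'   per-SNP effects are heterogeneous (IVW Q p < `alpha_heterogeneity`),
#'   which is inconsistent with a single liability pathway and points to a
#'   shared confounder; a significant Egger intercept
#'   (p < `alpha_pleiotropy`) likewise downgrades an otherwise clean call;
#' * `"A"` (liability subphenotype) - homogeneous forward effect with weak
#'   evidence in the reverse direction: liability causes both the trait and
#'   the phenotype shift;
#' * `"C"` (bidirectional / ambiguous) - homogeneous forward effect and a
#'   significant reverse effect; the Steiger direction is appended as the
#'   most likely direction of effect.
#'
#' An absent reverse result or Steiger test is treated as unavailable and
#' noted, never as evidence.
#'
#' @param forward_ivw `mr_result` of the forward IVW (required; its `q_p`
#'   supplies the heterogeneity test).
#' @param forward_egger Optional `mr_result` from [mr_egger()] supplying the
#'   intercept test.
#' @param reverse_ivw Optional `mr_result` of the reverse IVW.
#' @param steiger Optional `steiger_result`.
#' @param alpha_effect,alpha_heterogeneity,alpha_pleiotropy Decision
#'   thresholds, all in (0, 1).
#' @return List of class `scenario_call`: `label` (`"A"`, `"B"`, `"C"` or
#'   `"null"`), the supporting booleans `forward_signif`, `homogeneous`,
#'   `intercept_null`, `reverse_signif`, `steiger_forward`, and a `narrative`
#'   string.
#' @export
classify_scenario <- function(forward_ivw, forward_egger = NULL,
                              reverse_ivw = NULL, steiger = NULL,
                              alpha_effect = 0.05,
                              alpha_heterogeneity = 0.05,
                              alpha_pleiotropy = 0.05) {
  for (a in c(alpha_effect, alpha_heterogeneity, alpha_pleiotropy)) {
    if (!is.finite(a) || a <= 0 || a >= 1) stop("alpha thresholds must be in (0, 1)")
  }
  if (is.null(forward_ivw$p)) stop("forward IVW result required")

  forward_signif <- forward_ivw$p < alpha_effect
  homogeneous <- is.null(forward_ivw$q_p) || is.na(forward_ivw$q_p) ||
    forward_ivw$q_p >= alpha_heterogeneity
  intercept_null <- is.null(forward_egger) ||
    forward_egger$intercept_p >= alpha_pleiotropy
  reverse_signif <- !is.null(reverse_ivw) && reverse_ivw$p < alpha_effect
  steiger_forward <- !is.null(steiger) &&
    steiger$direction == "exposure->outcome"

  notes <- character(0)
  if (is.null(reverse_ivw)) notes <- c(notes, "reverse MR unavailable")
  if (is.null(steiger)) notes <- c(notes, "Steiger test unavailable")

  if (!forward_signif) {
    label <- "null"
    narrative <- "no evidence of a forward effect of liability on the phenotype"
  } else if (!homogeneous) {
    label <- "B"
    narrative <- paste("forward effect present but heterogeneous across",
                       "instruments; consistent with a shared confounder",
                       "rather than a single liability pathway")
  } else if (!reverse_signif) {
    label <- "A"
    narrative <- paste("homogeneous forward effect with weak reverse",
                       "evidence: the phenotype shift behaves as a",
                       "subphenotype of genetic liability")
  } else {
    label <- "C"
    dir_note <- if (is.null(steiger)) "direction untested" else
      sprintf("most likely direction: %s", steiger$direction)
    narrative <- paste("forward and reverse effects both present",
                       "(bidirectional or substantially genetically",
                       sprintf("correlated); %s", dir_note))
  }
  if (label %in% c("A", "C") && !intercept_null) {
    label <- "B"
    narrative <- paste("directional pleiotropy detected by the Egger",
                       "intercept; call downgraded to the confounded",
                       "scenario")
  }
  if (length(notes)) narrative <- paste(narrative, "-", paste(notes, collapse = "; "))

  structure(list(label = label,
                 forward_signif = forward_signif,
                 homogeneous = homogeneous,
                 intercept_null = intercept_null,
                 reverse_signif = reverse_signif,
                 steiger_forward = steiger_forward,
                 narrative = narrative),
            class = "scenario_call")
}

#' @export
print.scenario_call <- function(x, ...) {
  cat(sprintf("Scenario %s: %s\n", x$label, x$narrative))
  invisible(x)
}
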