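#' Score thresholds for essentiality calls
#'
#' Container for the two decision thresholds: \code{tau_e} on E_score
#' (default 0.6) and \code{tau_p} on P_score (default 0.03). Both defaults
#' sit in the upper tail of the respective score distributions over the
#' training KOs.
#'
#' @param tau_e E_score threshold, in (0, 1).
#' @param tau_p P_score threshold, in (0, 1).
#' @return A list of class \code{eg_thresholds}.
#' @export
eg_thresholds <- function(tau_e = 0.6, tau_p = 0.03) {
  if (!(tau_e > 0 && tau_e < 1 && tau_p > 0 && tau_p < 1))
    .stopf("thresholds must lie strictly between 0 and 1")
  structure(list(tau_e = tau_e, tau_p = tau_p), class = "eg_thresholds")
}

#' Predict gene essentiality from KO scores
#'
#' Calls each gene essential or non-essential from its KO's scores. The
#' default \code{e_priority} rule weights the experimental score above the
#' annotation-derived one: when an E_score is available the call is made on
#' E_score alone (essential iff \code{e_score >= tau_e}); P_score is
#' consulted only when no E_score exists (essential iff
#' \code{p_score >= tau_p}). Genes without a KO, or whose KO has neither
#' score, are \code{unscored}. The alternative \code{either} rule calls a
#' gene essential when either score clears its threshold. Rows where the two
#' scores disagree about their thresholds are flagged in
#' \code{score_conflict} for user review.
#'
#' @param scores Score table from [score_all()].
#' @param genes Strain gene table ([read_strain_genes()]) for the strain
#'   being predicted.
#' @param thresholds An [eg_thresholds()] object.
#' @param rule \code{"e_priority"} (default) or \code{"either"}.
#' @return Data frame with columns \code{locus_tag}, \code{ko_id},
#'   \code{predicted} (\code{essential} / \code{nonessential} /
#'   \code{unscored}), \code{basis} (\code{e_score} / \code{p_score} /
#'   \code{none}) and logical \code{score_conflict}.
#' @export
predict_essentiality <- function(scores, genes,
                                 thresholds = eg_thresholds(),
                                 rule = c("e_priority", "either")) {
  rule <- match.arg(rule)
  stopifnot(inherits(thresholds, "eg_thresholds"))
  idx <- match(genes$ko_id, scores$ko_id)
  e <- scores$e_score[idx]
  p <- scores$p_score[idx]

  e_call <- !is.na(e) & e >= thresholds$tau_e
  p_call <- !is.na(p) & p >= thresholds$tau_p

  basis <- ifelse(!is.na(e), "e_score", ifelse(!is.na(p), "p_score", "none"))
  pred <- rep("unscored", nrow(genes))
  if (rule == "e_priority") {
    pred[basis == "e_score"] <- ifelse(e_call[basis == "e_score"],
                                       "essential", "nonessential")
    pred[basis == "p_score"] <- ifelse(p_call[basis == "p_score"],
                                       "essential", "nonessential")
  } else {
    scored <- basis != "none"
    pred[scored] <- ifelse(e_call[scored] | p_call[scored],
                           "essential", "nonessential")
  }
  conflict <- !is.na(e) & !is.na(p) & (e_call != p_call)

  data.frame(locus_tag = genes$locus_tag,
             ko_id = genes$ko_id,
             predicted = pred,
             basis = basis,
             score_conflict = conflict,
             stringsAsFactors = FALSE)
}

#' Confusion matrix of essentiality predictions against experiment
#'
#' Cross-tabulates predicted against experimentally determined essentiality.
#' Unscored genes are excluded (validation focuses on genes with a KO and a
#' score), as are scored genes with no experimental label (warned about).
#'
#' @param predictions Output of [predict_essentiality()].
#' @param truth Data frame with columns \code{locus_tag} and \code{label}
#'   (\code{essential_experimental} / \code{nonessential}); a strain gene
#'   table works directly.
#' @return A list of class \code{eg_confusion} with counts \code{tp},
#'   \code{fn}, \code{tn}, \code{fp}.
#' @export
confusion_matrix <- function(predictions, truth) {
  scored <- predictions[predictions$predicted != "unscored", , drop = FALSE]
  lab <- truth$label[match(scored$locus_tag, truth$locus_tag)]
  known <- !is.na(lab) & lab %in% c("essential_experimental", "nonessential")
  if (any(!known))
    .warnf("%d scored gene(s) without an experimental label excluded",
           sum(!known))
  scored <- scored[known, , drop = FALSE]
  lab <- lab[known]
  pred_ess <- scored$predicted == "essential"
  true_ess <- lab == "essential_experimental"
  structure(list(tp = sum(pred_ess & true_ess),
                 fn = sum(!pred_ess & true_ess),
                 tn = sum(!pred_ess & !true_ess),
                 fp = sum(pred_ess & !true_ess)),
            class = "eg_confusion")
}

#' @export
print.eg_confusion <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FN=%d TN=%d FP=%d (n=%d)\n",
              x$tp, x$fn, x$tn, x$fp, x$tp + x$fn + x$tn + x$fp))
  invisible(x)
}

#' Harmonic mean of sensitivity and precision
#'
#' \eqn{F = 2sp/(s+p)}; \code{NA} when both inputs are 0 or either is
#' missing.
#'
#' @param sensitivity,precision Numeric vectors in \code{[0, 1]}.
#' @return Numeric vector of F-measures.
#' @export
f_measure <- function(sensitivity, precision) {
  out <- 2 * sensitivity * precision / (sensitivity + precision)
  out[!is.na(sensitivity) & !is.na(precision) &
        sensitivity + precision == 0] <- NA_real_
  out
}

#' Classification metrics from a confusion matrix
#'
#' The five standard binary-classifier metrics: sensitivity TP/(TP+FN),
#' specificity TN/(TN+FP), precision TP/(TP+FP), accuracy
#' (TP+TN)/(TP+TN+FP+FN), and the F-measure (harmonic mean of sensitivity
#' and precision). A metric whose denominator is zero is reported \code{NA};
#' an all-zero matrix yields all \code{NA}.
#'
#' @param cm An \code{eg_confusion} from [confusion_matrix()], or any list
#'   with elements \code{tp}, \code{fn}, \code{tn}, \code{fp}.
#' @return Named numeric vector: \code{sensitivity}, \code{specificity},
#'   \code{precision}, \code{accuracy}, \code{f_measure}.
#' @export
classification_metrics <- function(cm) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(cm$tp, cm$tp + cm$fn)
  spec <- ratio(cm$tn, cm$tn + cm$fp)
  prec <- ratio(cm$tp, cm$tp + cm$fp)
  acc <- ratio(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn)
  f <- if (is.na(sens) || is.na(prec)) NA_real_ else f_measure(sens, prec)
  c(sensitivity = sens, specificity = spec, precision = prec,
    accuracy = acc, f_measure = f)
}
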