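# Class-selection fusion of two classifier outputs.
#
# CP denotes the presence-specialist classifier (trained on the local,
# presence-sensitive view), CA the absence-specialist (global view). For a
# test sample w with predicted labels CP(w), CA(w) and calibrated own-class
# scores mu(P|w,CP), mu(A|w,CA), the rules are:
#
#   (a) CP(w)=P and CA(w)=P                          -> P   (consensus)
#   (b) CP(w)=A and CA(w)=A                          -> A   (consensus)
#   (c) CA(w)=A, CP(w)=P, mu(A|CA) > mu(P|CP)        -> A   (conflict)
#   (d) CA(w)=A, CP(w)=P, mu(A|CA) < mu(P|CP)        -> P   (conflict)
#
# Two situations the rules leave open are policy-controlled rather than
# guessed: an exact score tie in the conflict case, and the reverse
# disagreement CP(w)=A, CA(w)=P, which (a)-(d) never cover.

#' Fusion policy: how the uncovered cases are resolved
#'
#' @param tie_rule Label assigned on an exact score tie in the conflict
#'   case: `"prefer_P"` (default; a missed dysplastic lesion is the
#'   costlier error) or `"prefer_A"`.
#' @param uncovered_rule Resolution of the reverse disagreement
#'   `CP = A, CA = P`: `"confidence_vote"` (default; extends the conflict
#'   rules' own principle — the classifier with the larger score for its own
#'   predicted class wins, ties per `tie_rule`) or `"prefer_specialist"`
#'   (CP decides P-membership, so the outcome is A).
#' @param score_rule Construction of the fused presence score used for ROC
#'   analysis: `"selected_classifier"` (default; the winning classifier's
#'   `score_P`) or `"average"` (mean of the two `score_P`s).
#' @return An object of class `fusion_policy`.
#' @export
fusion_policy <- function(tie_rule = c("prefer_P", "prefer_A"),
                          uncovered_rule = c("confidence_vote", "prefer_specialist"),
                          score_rule = c("selected_classifier", "average")) {
  structure(list(
    tie_rule = match.arg(tie_rule),
    uncovered_rule = match.arg(uncovered_rule),
    score_rule = match.arg(score_rule)
  ), class = "fusion_policy")
}

#' Fuse two classifier outputs by class selection
#'
#' Applies the four class-selection rules (see the policy documentation and
#' the package vignette) per sample: consensus is kept; on the conflict
#' `CP = P, CA = A` the larger own-class confidence wins; score ties and the
#' reverse disagreement are resolved per `policy`. Exactly one rule fires
#' per sample and is reported in `rule_fired` (`a`, `b`, `c`, `d`, `tie`, or
#' `uncovered`).
#'
#' @param out_CP [classifier_output()] of the presence-specialist classifier.
#' @param out_CA [classifier_output()] of the absence-specialist classifier,
#'   with the identical sample id sequence.
#' @param policy A [fusion_policy()].
#' @return An object of class `fusion_decisions`: a `data.frame` with
#'   columns `sample_id`, `fused_label`, `fused_score_P`, `rule_fired`,
#'   `selected` (which classifier's score was taken).
#' @export
fuse_outputs <- function(out_CP, out_CA, policy = fusion_policy()) {
  if (length(out_CP$sample_id) != length(out_CA$sample_id) ||
      any(out_CP$sample_id != out_CA$sample_id)) {
    bad <- which(out_CP$sample_id[seq_len(min(nrow(out_CP), nrow(out_CA)))] !=
                   out_CA$sample_id[seq_len(min(nrow(out_CP), nrow(out_CA)))])[1]
    stop_input("sample id sequences differ between classifier outputs",
               if (!is.na(bad)) paste0(" (first mismatch at position ", bad, ": '",
                                       out_CP$sample_id[bad], "' vs '",
                                       out_CA$sample_id[bad], "')")
               else paste0(" (lengths ", nrow(out_CP), " vs ", nrow(out_CA), ")"))
  }
  n <- nrow(out_CP)
  fused <- character(n)
  rule <- character(n)
  selected <- character(n)

  lp <- out_CP$label
  la <- out_CA$label
  mu_P_CP <- out_CP$score_P  # CP's confidence in its P call
  mu_A_CA <- out_CA$score_A  # CA's confidence in its A call
  mu_A_CP <- out_CP$score_A
  mu_P_CA <- out_CA$score_P
  tie_label <- if (policy$tie_rule == "prefer_P") "P" else "A"

  for (i in seq_len(n)) {
    if (lp[i] == "P" && la[i] == "P") {            # (a) consensus P
      fused[i] <- "P"; rule[i] <- "a"; selected[i] <- "CP"
    } else if (lp[i] == "A" && la[i] == "A") {     # (b) consensus A
      fused[i] <- "A"; rule[i] <- "b"; selected[i] <- "CA"
    } else if (lp[i] == "P" && la[i] == "A") {     # conflict of evidence
      if (mu_A_CA[i] > mu_P_CP[i]) {
        fused[i] <- "A"; rule[i] <- "c"; selected[i] <- "CA"
      } else if (mu_A_CA[i] < mu_P_CP[i]) {
        fused[i] <- "P"; rule[i] <- "d"; selected[i] <- "CP"
      } else {
        fused[i] <- tie_label; rule[i] <- "tie"
        selected[i] <- if (tie_label == "P") "CP" else "CA"
      }
    } else {                                       # uncovered: CP=A, CA=P
      rule[i] <- "uncovered"
      if (policy$uncovered_rule == "prefer_specialist") {
        fused[i] <- "A"; selected[i] <- "CP"
      } else if (mu_A_CP[i] > mu_P_CA[i]) {
        fused[i] <- "A"; selected[i] <- "CP"
      } else if (mu_A_CP[i] < mu_P_CA[i]) {
        fused[i] <- "P"; selected[i] <- "CA"
      } else {
        fused[i] <- tie_label
        selected[i] <- if (tie_label == "P") "CA" else "CP"
      }
    }
  }

  score <- if (policy$score_rule == "average") {
    (out_CP$score_P + out_CA$score_P) / 2
  } else {
    ifelse(selected == "CP", out_CP$score_P, out_CA$score_P)
  }

  structure(data.frame(
    sample_id = out_CP$sample_id,
    fused_label = fused,
    fused_score_P = score,
    rule_fired = rule,
    selected = selected,
    stringsAsFactors = FALSE
  ), class = c("fusion_decisions", "data.frame"))
}

#' Export fusion decisions to CSV
#'
#' @param decisions A `fusion_decisions` object from [fuse_outputs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fusion_decisions <- function(decisions, path) {
  utils::write.csv(
    decisions[, c("sample_id", "fused_label", "fused_score_P", "rule_fired")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
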