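# Substitution scoring: log-ratio of mutant to wild-type match-state
# emission probabilities, optionally modulated by pathogenicity weights.
#
# The score is a pluggable strategy. Both strategies satisfy the same
# contract: zero when P_m = P_w (with neutral weights), strictly
# increasing in P_m, strictly decreasing in P_w, negative scores mark
# unfavorable substitutions and positive scores favorable ones.
#   ratio: S = ln(P_m / P_w)            [default]
#   odds:  S = ln[(P_m/(1-P_m)) / (P_w/(1-P_w))]

PROB_EPSILON <- 1e-10

floor_prob <- function(p, epsilon = PROB_EPSILON, what = "probability") {
  if (p < epsilon) {
    warning(what, " ", format(p), " floored at epsilon ", format(epsilon))
    epsilon
  } else p
}

#' Unweighted substitution score
#'
#' The predicted magnitude of effect of replacing the wild-type residue
#' (emission probability `p_wild`) with the mutant residue (`p_mutant`)
#' at the interrogated match state. With the default `"ratio"` strategy
#' this is `ln(p_mutant / p_wild)`; the `"odds"` strategy uses the
#' log-odds-ratio form. Zero-probability inputs are floored at `epsilon`
#' with a warning so scores stay finite.
#'
#' @param p_wild,p_mutant match-state emission probabilities of the
#'   wild-type and mutant residues.
#' @param formula `"ratio"` (default) or `"odds"`.
#' @param epsilon flooring constant for zero probabilities
#'   (default 1e-10).
#' @return the score in natural-log units; negative = unfavorable.
#' @export
unweighted_score <- function(p_wild, p_mutant, formula = c("ratio", "odds"),
                             epsilon = PROB_EPSILON) {
  formula <- match.arg(formula)
  p_wild <- floor_prob(p_wild, epsilon, "wild-type probability")
  p_mutant <- floor_prob(p_mutant, epsilon, "mutant probability")
  if (formula == "ratio")
    log(p_mutant / p_wild)
  else
    log((p_mutant / (1 - p_mutant)) / (p_wild / (1 - p_wild)))
}

#' Weighted substitution score
#'
#' Modulates the unweighted score by the pathogenicity weights of the
#' interrogated model: with the default `"ratio"` strategy,
#' `S = ln((p_mutant * w_n) / (p_wild * w_d))`, i.e. the unweighted score
#' plus the constant `ln(w_n / w_d)`. A domain enriched for
#' disease-associated substitutions (`w_d > w_n`) shifts every score
#' downwards, toward damaging. Reduces exactly to [unweighted_score()]
#' when `w_d == w_n`.
#'
#' @inheritParams unweighted_score
#' @param w_d,w_n strictly positive pathogenicity weights
#'   (see [weights_for()]).
#' @return the weighted score in natural-log units.
#' @export
weighted_score <- function(p_wild, p_mutant, w_d, w_n,
                           formula = c("ratio", "odds"),
                           epsilon = PROB_EPSILON) {
  if (w_d <= 0 || w_n <= 0)
    stop("pathogenicity weights must be strictly positive")
  unweighted_score(p_wild, p_mutant, formula, epsilon) + log(w_n / w_d)
}

#' Classify a score against a threshold
#'
#' A substitution is called damaging when its score falls strictly below
#' the threshold; scores at or above it (ties included) are tolerated.
#' Defaults are -3.0 for the unweighted method and -1.5 for the weighted
#' one, as calibrated at the point where sensitivity and specificity are
#' jointly maximized.
#'
#' @param score numeric score(s).
#' @param threshold classification threshold.
#' @return character vector, `"damaging"` or `"tolerated"`.
#' @export
classify <- function(score, threshold) {
  ifelse(score < threshold, "damaging", "tolerated")
}

#' Default thresholds for the two methods
#' @param method `"unweighted"` or `"weighted"`.
#' @return the default threshold (-3.0 or -1.5).
#' @export
default_threshold <- function(method = c("unweighted", "weighted")) {
  switch(match.arg(method), unweighted = -3.0, weighted = -1.5)
}

#' Score one substitution end to end
#'
#' Runs the full pipeline: filter hits for significance, enumerate
#' candidate models covering the substitution at a match state, rank them
#' by Kullback-Leibler information content, interrogate the most
#' informative model for the wild-type and mutant emission probabilities,
#' score (weighted when a weight table is supplied, else unweighted) and
#' classify. With no covering candidate the call is `no_prediction`.
#' Weighted mode is restricted to library domains: ab initio models are
#' excluded from its candidate set, because pathogenicity weights exist
#' only for library domains.
#'
#' @param sub a [substitution()].
#' @param hits list of [domain_hit()] objects.
#' @param library named list of [profile_hmm()] objects.
#' @param weights optional `WeightTable`; switches on weighted scoring.
#' @param e_threshold significance threshold (default 0.01).
#' @param threshold classification threshold; defaults to the method's
#'   calibrated value via [default_threshold()].
#' @param formula score strategy, `"ratio"` or `"odds"`.
#' @param background optional global composition override for model
#'   ranking (path or named vector).
#' @param epsilon probability floor (default 1e-10).
#' @param normalized_weights use the relative-frequency weight form.
#' @param window information window for [rank_candidates()].
#' @return a one-row data.frame of class `Prediction` with columns
#'   `protein_id, position, wild_type, mutant, model_id, state_index,
#'   p_wild, p_mutant, score, method, call, threshold, low_support`.
#' @export
predict_substitution <- function(sub, hits, library, weights = NULL,
                                 e_threshold = 0.01, threshold = NULL,
                                 formula = c("ratio", "odds"),
                                 background = NULL,
                                 epsilon = PROB_EPSILON,
                                 normalized_weights = FALSE,
                                 window = 1L) {
  formula <- match.arg(formula)
  method <- if (is.null(weights)) "unweighted" else "weighted"
  if (is.null(threshold)) threshold <- default_threshold(method)

  sig <- significant_hits(hits, e_threshold)
  cands <- candidate_models(sub, sig, library)
  if (method == "weighted")
    cands <- Filter(function(cand) cand$model$source != "ab_initio", cands)

  base <- data.frame(
    protein_id = sub$protein_id, position = sub$position,
    wild_type = sub$wild_type, mutant = sub$mutant,
    model_id = NA_character_, state_index = NA_integer_,
    p_wild = NA_real_, p_mutant = NA_real_, score = NA_real_,
    method = method, call = "no_prediction", threshold = threshold,
    low_support = FALSE, stringsAsFactors = FALSE
  )
  class(base) <- c("Prediction", "data.frame")
  if (!length(cands)) return(base)

  ranking <- rank_candidates(cands, background = background,
                             window = window)
  best <- ranking[1L, ]
  model <- library[[best$model_id]]
  pw <- emission_probability(model, best$state_index, sub$wild_type)
  pm <- emission_probability(model, best$state_index, sub$mutant)
  low_support <- pw < epsilon
  score <- withCallingHandlers(
    if (method == "weighted") {
      w <- weights_for(best$model_id, weights,
                       normalized = normalized_weights)
      weighted_score(pw, pm, w[["w_d"]], w[["w_n"]], formula, epsilon)
    } else {
      unweighted_score(pw, pm, formula, epsilon)
    },
    warning = function(w) invokeRestart("muffleWarning")
  )
  base$model_id <- best$model_id
  base$state_index <- best$state_index
  base$p_wild <- pw
  base$p_mutant <- pm
  base$score <- score
  base$call <- classify(score, threshold)
  base$low_support <- low_support
  base
}

#' Score a table of substitutions
#'
#' Vectorized front end over [predict_substitution()].
#'
#' @param subs data.frame with columns `protein_id, position, wild_type,
#'   mutant` (extra columns such as `label` are carried through).
#' @inheritParams predict_substitution
#' @return a data.frame with one prediction row per input row.
#' @export
predict_substitutions <- function(subs, hits, library, weights = NULL, ...) {
  rows <- lapply(seq_len(nrow(subs)), function(r) {
    sub <- substitution(subs$protein_id[[r]], subs$position[[r]],
                        subs$wild_type[[r]], subs$mutant[[r]])
    predict_substitution(sub, hits, library, weights, ...)
  })
  out <- do.call(rbind, rows)
  extra <- setdiff(names(subs), names(out))
  for (cn in extra) out[[cn]] <- subs[[cn]]
  rownames(out) <- NULL
  out
}

#' Read an unlabeled substitution table
#'
#' Tab-separated columns `protein_id, position, wild_type, mutant`.
#'
#' @param path input file.
#' @return data.frame with those four columns.
#' @export
read_substitutions <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("protein_id", "position", "wild_type",
                                  "mutant"),
                    colClasses = c("character", "integer", "character",
                                   "character"))
}
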