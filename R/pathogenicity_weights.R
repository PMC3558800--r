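# Domain-level pathogenicity weights: counts of disease-associated and
# neutral substitutions mapping onto each model, plus a pseudo-count of
# 1.0 so the weight ratio is always defined.

#' Read a labeled substitution table
#'
#' Tab-separated columns `protein_id, position, wild_type, mutant, label`
#' with label in `{disease, neutral}`.
#'
#' @param path input file.
#' @return data.frame with those five columns.
#' @export
read_labeled_substitutions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("protein_id", "position",
                                        "wild_type", "mutant", "label"),
                          colClasses = c("character", "integer",
                                         "character", "character",
                                         "character"))
  bad <- !df$label %in% c("disease", "neutral")
  if (any(bad))
    stop("unknown label(s): ", paste(unique(df$label[bad]), collapse = ", "))
  df
}

#' Count disease/neutral substitutions mapping onto each model
#'
#' Each labeled substitution increments the disease or neutral count of
#' every model it maps onto through a significant domain hit at a match
#' state; substitutions covered by no model contribute nothing. Duplicate
#' records (same protein, position, wild-type, mutant and label) are
#' counted once.
#'
#' @param mutations data.frame with columns `protein_id, position,
#'   wild_type, mutant, label` (label in `disease`/`neutral`), as read by
#'   [read_labeled_substitutions()].
#' @param hits list of [domain_hit()] objects.
#' @param library named list of [profile_hmm()] objects.
#' @param e_threshold significance threshold applied to `hits`
#'   (default 0.01).
#' @param pseudo_count pseudo-count added when weights are derived
#'   (default 1.0).
#' @return a `WeightTable`: list with `counts` (data.frame `model_id`,
#'   `disease_count`, `neutral_count`), `pseudo_count`, and the dataset
#'   totals `total_disease` / `total_neutral` (sums over models).
#' @export
count_mappings <- function(mutations, hits, library, e_threshold = 0.01,
                           pseudo_count = 1.0) {
  if (!all(mutations$label %in% c("disease", "neutral")))
    stop("labels must be 'disease' or 'neutral'")
  key <- paste(mutations$protein_id, mutations$position,
               mutations$wild_type, mutations$mutant, mutations$label,
               sep = "\r")
  mutations <- mutations[!duplicated(key), , drop = FALSE]
  sig <- significant_hits(hits, e_threshold)
  tal <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(mutations))) {
    sub <- substitution(mutations$protein_id[[r]],
                        mutations$position[[r]],
                        mutations$wild_type[[r]],
                        mutations$mutant[[r]])
    cands <- candidate_models(sub, sig, library)
    for (cand in cands) {
      id <- cand$model$model_id
      cur <- if (is.null(tal[[id]])) c(disease = 0L, neutral = 0L)
             else tal[[id]]
      lab <- mutations$label[[r]]
      cur[[lab]] <- cur[[lab]] + 1L
      tal[[id]] <- cur
    }
  }
  ids <- sort(ls(tal))
  counts <- data.frame(
    model_id = ids,
    disease_count = vapply(ids, function(i) tal[[i]][["disease"]],
                           integer(1)),
    neutral_count = vapply(ids, function(i) tal[[i]][["neutral"]],
                           integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  weight_table(counts, pseudo_count = pseudo_count)
}

#' Construct a weight table from per-model counts
#'
#' @param counts data.frame with columns `model_id`, `disease_count`,
#'   `neutral_count` (non-negative integers).
#' @param pseudo_count positive pseudo-count (default 1.0).
#' @return a `WeightTable` object.
#' @export
weight_table <- function(counts, pseudo_count = 1.0) {
  stopifnot(pseudo_count > 0,
            all(c("model_id", "disease_count", "neutral_count") %in%
                names(counts)))
  if (any(counts$disease_count < 0) || any(counts$neutral_count < 0))
    stop("counts must be non-negative")
  if (anyDuplicated(counts$model_id))
    stop("duplicate model_id in counts")
  structure(list(counts = counts, pseudo_count = pseudo_count,
                 total_disease = sum(counts$disease_count),
                 total_neutral = sum(counts$neutral_count)),
            class = "WeightTable")
}

#' @export
print.WeightTable <- function(x, ...) {
  cat("WeightTable:", nrow(x$counts), "models, totals d =",
      x$total_disease, "/ n =", x$total_neutral,
      ", pseudo-count", x$pseudo_count, "\n")
  invisible(x)
}

#' Pathogenicity weights for one model
#'
#' The default (unnormalized) form is `W_d = c_d + pseudo`,
#' `W_n = c_n + pseudo`; a model unknown to the table has zero counts and
#' therefore neutral weights. The `normalized = TRUE` variant divides by
#' pseudo-counted dataset totals, `W = (c + pseudo) / (T + pseudo)`;
#' because only the ratio `W_n / W_d` enters the weighted score, the two
#' forms differ by the constant offset `ln((T_d + pseudo)/(T_n + pseudo))`
#' applied to every weighted score.
#'
#' @param model_id model identifier.
#' @param table a `WeightTable`.
#' @param normalized use the relative-frequency form (default `FALSE`).
#' @return named numeric vector `c(w_d = ..., w_n = ...)`, both > 0.
#' @export
weights_for <- function(model_id, table, normalized = FALSE) {
  stopifnot(inherits(table, "WeightTable"))
  i <- match(model_id, table$counts$model_id)
  cd <- if (is.na(i)) 0 else table$counts$disease_count[[i]]
  cn <- if (is.na(i)) 0 else table$counts$neutral_count[[i]]
  pc <- table$pseudo_count
  if (normalized)
    c(w_d = (cd + pc) / (table$total_disease + pc),
      w_n = (cn + pc) / (table$total_neutral + pc))
  else
    c(w_d = cd + pc, w_n = cn + pc)
}

#' Leave-one-out adjustment of a weight table
#'
#' When the substitution being evaluated is itself present in the
#' training counts, its own contribution is removed before scoring to
#' avoid circularity: the matching label's count is decremented by one on
#' every model the substitution was counted into. A substitution absent
#' from the training data leaves the table unchanged. The input table is
#' not modified.
#'
#' @param table a `WeightTable`.
#' @param sub the [substitution()] under evaluation.
#' @param label its label in the training data, `"disease"` or
#'   `"neutral"`.
#' @param hits,library,e_threshold the same hit set, model library and
#'   significance threshold used by [count_mappings()], so membership is
#'   decided identically.
#' @param training optional labeled substitution table the counts were
#'   built from; when given, the adjustment is applied only if the exact
#'   record `(protein_id, position, wild_type, mutant, label)` occurs in
#'   it, and the table is returned unchanged otherwise. When omitted the
#'   record is assumed to have been counted.
#' @return an adjusted `WeightTable`.
#' @export
leave_one_out <- function(table, sub, label, hits, library,
                          e_threshold = 0.01, training = NULL) {
  stopifnot(inherits(table, "WeightTable"),
            label %in% c("disease", "neutral"))
  if (!is.null(training)) {
    present <- any(training$protein_id == sub$protein_id &
                     training$position == sub$position &
                     training$wild_type == sub$wild_type &
                     training$mutant == sub$mutant &
                     training$label == label)
    if (!present) return(table)
  }
  cands <- candidate_models(sub, significant_hits(hits, e_threshold),
                            library)
  if (!length(cands)) return(table)
  counts <- table$counts
  col <- paste0(if (label == "disease") "disease" else "neutral", "_count")
  for (cand in cands) {
    i <- match(cand$model$model_id, counts$model_id)
    if (is.na(i)) next
    if (counts[[col]][[i]] < 1L)
      stop("leave-one-out would drive ", col, " of model '",
           cand$model$model_id, "' below zero")
    counts[[col]][[i]] <- counts[[col]][[i]] - 1L
  }
  weight_table(counts, pseudo_count = table$pseudo_count)
}

#' Write / read weight tables
#'
#' Serialized as tab-separated `model_id, disease_count, neutral_count`.
#'
#' @param table a `WeightTable`.
#' @param path file path.
#' @return `path` (write) or a `WeightTable` (read).
#' @export
write_weight_table <- function(table, path) {
  stopifnot(inherits(table, "WeightTable"))
  utils::write.table(table$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_table
#' @param pseudo_count pseudo-count for the read table (default 1.0).
#' @export
read_weight_table <- function(path, pseudo_count = 1.0) {
  counts <- utils::read.table(path, sep = "\t", header = FALSE,
                              col.names = c("model_id", "disease_count",
                                            "neutral_count"),
                              colClasses = c("character", "integer",
                                             "integer"))
  weight_table(counts, pseudo_count = pseudo_count)
}
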