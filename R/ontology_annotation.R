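# Domain-centric ontology annotation: molecular/phenotypic terms are
# transferred to damaging predictions through precomputed model -> term
# mapping tables (e.g. a dcGO-style domain-to-GO/phenotype mapping).

#' Read a domain-to-ontology-term mapping table
#'
#' Tab-separated columns `model_id, term_id, term_name, ontology_name`
#' with an optional fifth column carrying an association score. Duplicate
#' rows are collapsed.
#'
#' @param path input file.
#' @return data.frame of class `TermMapping` with columns `model_id,
#'   term_id, term_name, ontology_name, score` (score `NA` when absent).
#' @export
read_term_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  for (r in seq_along(rows)) {
    f <- rows[[r]]
    if (length(f) < 4L || any(!nzchar(f[1:4])))
      stop("row ", r, ": expected at least 4 non-empty tab-separated ",
           "fields (model_id, term_id, term_name, ontology_name)")
    if (length(f) > 5L)
      stop("row ", r, ": too many fields (", length(f), ")")
  }
  df <- data.frame(
    model_id = vapply(rows, `[[`, character(1), 1L),
    term_id = vapply(rows, `[[`, character(1), 2L),
    term_name = vapply(rows, `[[`, character(1), 3L),
    ontology_name = vapply(rows, `[[`, character(1), 4L),
    score = vapply(rows, function(f)
      if (length(f) >= 5L) suppressWarnings(as.numeric(f[[5L]]))
      else NA_real_, numeric(1)),
    stringsAsFactors = FALSE
  )
  df <- df[!duplicated(df[c("model_id", "term_id")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("TermMapping", "data.frame")
  df
}

#' Annotate a prediction with ontology terms
#'
#' Transfers the terms mapped to the prediction's model. By default only
#' damaging calls are annotated (the consequence annotation applies to
#' pathogenic substitutions); `calls` widens this. Predictions without a
#' model, or whose model has no mapping, yield an empty set.
#'
#' @param pred a one-row prediction (from [predict_substitution()]).
#' @param mapping a `TermMapping` from [read_term_map()].
#' @param calls calls eligible for annotation (default `"damaging"`).
#' @param ontology optional term graph from [read_obo()]; when given,
#'   each mapped term is expanded to include its `is_a` ancestors.
#' @return data.frame of the prediction's terms (possibly zero rows) with
#'   columns `term_id, term_name, ontology_name, score`.
#' @export
annotate_prediction <- function(pred, mapping, calls = "damaging",
                                ontology = NULL) {
  stopifnot(inherits(mapping, "TermMapping"))
  empty <- mapping[0L, c("term_id", "term_name", "ontology_name", "score")]
  if (is.na(pred$model_id[[1L]]) || !pred$call[[1L]] %in% calls)
    return(empty)
  hit <- mapping$model_id == pred$model_id[[1L]]
  if (!any(hit)) {
    message("no ontology terms mapped to model '", pred$model_id[[1L]], "'")
    return(empty)
  }
  out <- mapping[hit, c("term_id", "term_name", "ontology_name", "score"),
                 drop = FALSE]
  if (!is.null(ontology)) {
    anc <- unique(unlist(lapply(out$term_id, obo_ancestors,
                                ontology = ontology)))
    anc <- setdiff(anc, out$term_id)
    if (length(anc))
      out <- rbind(out, data.frame(
        term_id = anc,
        term_name = unname(ontology$names[anc]),
        ontology_name = out$ontology_name[[1L]],
        score = NA_real_, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Read a minimal OBO 1.2 term graph
#'
#' Parses `[Term]` stanzas for `id`, `name` and `is_a` edges only; this
#' supports term-name lookup and ancestor expansion, not full OBO
#' semantics.
#'
#' @param path OBO file.
#' @return list with `names` (id -> name) and `parents` (id -> character
#'   vector of direct `is_a` parents).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  names_map <- character(0)
  parents <- list()
  id <- NULL; in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { in_term <- TRUE; id <- NULL; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      id <- trimws(sub("^id:", "", ln))
      parents[[id]] <- character(0)
    } else if (startsWith(ln, "name:") && !is.null(id)) {
      names_map[[id]] <- trimws(sub("^name:", "", ln))
    } else if (startsWith(ln, "is_a:") && !is.null(id)) {
      parent <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      parents[[id]] <- c(parents[[id]], parent)
    }
  }
  list(names = names_map, parents = parents)
}

# All is_a ancestors of a term (excluding the term itself).
obo_ancestors <- function(term_id, ontology) {
  seen <- character(0)
  frontier <- ontology$parents[[term_id]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(ontology$parents[new]))
  }
  seen
}
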