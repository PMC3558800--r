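# Per-match-state information content and most-informative-model
# selection. Units are nats throughout (natural logarithm), so the KL
# information content and the substitution scores share one log base.

#' Kullback-Leibler information content of an emission distribution
#'
#' Computes `sum_a p(a) * ln(p(a) / q(a))` of a match state's emission
#' probabilities `p` against a background composition `q`, with the
#' standard convention `0 * ln(0/q) = 0`. This is the information gained
#' by the match state over the background, in nats; it is zero exactly
#' when the emissions equal the background.
#'
#' @param emissions 20-vector of emission probabilities (sums to 1).
#' @param background a `BackgroundComposition` (see
#'   [background_composition()]) or a bare 20-vector of probabilities.
#' @return non-negative information content in nats.
#' @export
information_content <- function(emissions, background) {
  q <- if (inherits(background, "BackgroundComposition"))
    background$probabilities else as.numeric(background)
  p <- as.numeric(emissions)
  if (length(p) != length(q))
    stop("emissions and background must have equal length")
  if (abs(sum(p) - 1) > 1e-6)
    stop("emissions must sum to 1")
  if (any(q <= 0 & p > 0))
    stop("background has zero mass where emissions are positive")
  nz <- p > 0
  max(0, sum(p[nz] * log(p[nz] / q[nz])))
}

#' Rank candidate models by match-state information content
#'
#' Orders candidates by decreasing information content of the match state
#' each one resolves the substitution to; the head of the list is the
#' most informative model, the one interrogated for scoring. Each
#' candidate is measured against its own resolved background (its COMPO
#' line when present, else uniform) unless a global composition is
#' supplied, which overrides every model's background for cross-model
#' comparability. Ties break by library priority (superfamily > Pfam-A >
#' Pfam-B > ab initio), then lexicographic model id.
#'
#' @param candidates list from [candidate_models()]: each element a list
#'   with `model` and `state_index`.
#' @param background optional global composition (path or named vector)
#'   passed to [background_composition()] as the override.
#' @param window odd integer; 1 (default) compares information at the
#'   single match state, larger values average information over a centred
#'   window of states, clipped at model ends.
#' @return a data.frame with columns `model_id`, `state_index`, `value`
#'   (nats), `source`, ordered by the ranking; zero rows when
#'   `candidates` is empty.
#' @export
rank_candidates <- function(candidates, background = NULL, window = 1L) {
  window <- as.integer(window)
  stopifnot(window >= 1L, window %% 2L == 1L)
  n <- length(candidates)
  if (n == 0L)
    return(data.frame(model_id = character(0), state_index = integer(0),
                      value = numeric(0), source = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(candidates, function(cand) {
    m <- cand$model
    bg <- background_composition(m, override = background)
    half <- (window - 1L) %/% 2L
    states <- max(1L, cand$state_index - half):
              min(m$length, cand$state_index + half)
    vals <- vapply(states, function(s)
      information_content(m$match_emissions[s, ], bg), numeric(1))
    data.frame(model_id = m$model_id, state_index = cand$state_index,
               value = mean(vals), source = m$source,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  prio <- match(out$source, MODEL_SOURCES)
  out <- out[order(-out$value, prio, out$model_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
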