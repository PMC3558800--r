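# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# A model whose every match state is uniform over the 20 residues.
uniform_model <- function(length = 5L, model_id = "UNIF1",
                          source = "ab_initio") {
  emis <- matrix(1 / 20, nrow = length, ncol = 20L,
                 dimnames = list(NULL, AA))
  profile_hmm(model_id, emis, source = source)
}

# A model with a point mass (up to epsilon spread) on one residue per
# state; `consensus` is a vector of residue letters recycled to length.
peaked_model <- function(length = 5L, consensus = "A", peak = 0.99,
                         model_id = "PEAK1", source = "pfam_a") {
  consensus <- rep_len(consensus, length)
  emis <- matrix((1 - peak) / 19, nrow = length, ncol = 20L,
                 dimnames = list(NULL, AA))
  emis[cbind(seq_len(length), match(consensus, AA))] <- peak
  profile_hmm(model_id, emis, source = source)
}

# Random stochastic 20-vector.
random_simplex <- function() {
  x <- stats::rexp(20L)
  x / sum(x)
}

# Brute-force KL oracle: explicit 20-term loop, independent of
# information_content().
kl_oracle <- function(p, q) {
  total <- 0
  for (a in seq_along(p)) {
    if (p[[a]] > 0) total <- total + p[[a]] * log(p[[a]] / q[[a]])
  }
  total
}

# Brute-force AUC oracle over all threshold placements (strict rule:
# score < t calls positive), trapezoid integration.
auc_oracle <- function(scores, positive) {
  ts <- sort(unique(c(-Inf, Inf,
                      (sort(unique(scores))[-1] +
                       utils::head(sort(unique(scores)), -1)) / 2)))
  pts <- t(sapply(ts, function(t) {
    called <- scores < t
    c(fpr = sum(called & !positive) / sum(!positive),
      tpr = sum(called & positive) / sum(positive))
  }))
  pts <- pts[order(pts[, "fpr"], pts[, "tpr"]), , drop = FALSE]
  sum(diff(pts[, "fpr"]) *
        (utils::head(pts[, "tpr"], -1) + utils::tail(pts[, "tpr"], -1)) / 2)
}

# Independent end-to-end prediction oracle: enumerate every significant
# hit covering the substitution at a match state, recompute KL by the
# explicit loop, pick the most informative candidate (library priority,
# then model id on ties) and recompute the score from raw emissions.
predict_oracle <- function(sub, hits, library, weights = NULL,
                           e_threshold = 0.01, epsilon = 1e-10) {
  src_rank <- c(superfamily = 1, pfam_a = 2, pfam_b = 3, ab_initio = 4)
  best <- NULL
  for (h in hits) {
    if (h$e_value > e_threshold) next
    if (h$protein_id != sub$protein_id) next
    if (sub$position < h$ali_from || sub$position > h$ali_to) next
    st <- h$state_map[[sub$position - h$ali_from + 1L]]
    if (is.na(st)) next
    m <- library[[h$model_id]]
    if (is.null(m)) next
    if (!is.null(weights) && m$source == "ab_initio") next
    bg <- rep(1 / 20, 20L)
    if (!is.null(m$compo)) bg <- m$compo / sum(m$compo)
    info <- kl_oracle(m$match_emissions[st, ], bg)
    key <- list(info = info, rank = src_rank[[m$source]],
                id = m$model_id)
    better <- is.null(best) || key$info > best$info + 1e-15 ||
      (abs(key$info - best$info) <= 1e-15 &&
         (key$rank < best$rank ||
            (key$rank == best$rank && key$id < best$id)))
    if (better)
      best <- c(key, list(model = m, state = st))
  }
  if (is.null(best)) return(NULL)
  pw <- max(best$model$match_emissions[best$state, sub$wild_type], epsilon)
  pm <- max(best$model$match_emissions[best$state, sub$mutant], epsilon)
  score <- log(pm / pw)
  if (!is.null(weights)) {
    i <- match(best$model$model_id, weights$counts$model_id)
    cd <- if (is.na(i)) 0 else weights$counts$disease_count[[i]]
    cn <- if (is.na(i)) 0 else weights$counts$neutral_count[[i]]
    score <- score + log((cn + weights$pseudo_count) /
                           (cd + weights$pseudo_count))
  }
  list(model_id = best$model$model_id, state = best$state, score = score)
}
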