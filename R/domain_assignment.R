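# Domain hits: significant assignments of profile HMMs onto proteins,
# with a per-residue map from protein positions to model match states.

#' Construct a domain hit
#'
#' A `DomainHit` records one assignment of a profile HMM onto a protein:
#' the aligned region in 1-based inclusive protein coordinates, the hit's
#' e-value, and a state map giving, for every aligned protein position,
#' either the 1-based match-state index it occupies or `NA` for positions
#' emitted by an insert state.
#'
#' @param protein_id protein identifier.
#' @param model_id model identifier (must match a library model to score).
#' @param e_value non-negative e-value of the assignment.
#' @param ali_from,ali_to 1-based inclusive protein coordinates.
#' @param state_map integer vector of length `ali_to - ali_from + 1`:
#'   match-state index per aligned position, `NA` for inserts. Match-state
#'   indices must be strictly increasing along the protein.
#' @return an object of class `DomainHit`.
#' @export
domain_hit <- function(protein_id, model_id, e_value, ali_from, ali_to,
                       state_map) {
  ali_from <- as.integer(ali_from); ali_to <- as.integer(ali_to)
  if (is.na(ali_from) || is.na(ali_to) || ali_from > ali_to)
    stop("invalid alignment envelope: ali_from (", ali_from,
         ") > ali_to (", ali_to, ")")
  if (!is.numeric(e_value) || is.na(e_value) || e_value < 0)
    stop("e_value must be a non-negative number")
  state_map <- as.integer(state_map)
  if (length(state_map) != ali_to - ali_from + 1L)
    stop("state_map must cover every position in [ali_from, ali_to]")
  idx <- state_map[!is.na(state_map)]
  if (length(idx) && any(diff(idx) <= 0L))
    stop("match-state indices must be strictly increasing along the protein")
  structure(list(
    protein_id = as.character(protein_id),
    model_id = as.character(model_id),
    e_value = as.numeric(e_value),
    ali_from = ali_from, ali_to = ali_to,
    state_map = state_map
  ), class = "DomainHit")
}

#' @export
print.DomainHit <- function(x, ...) {
  cat(sprintf("DomainHit %s ~ %s [%d-%d] e=%g (%d match positions)\n",
              x$protein_id, x$model_id, x$ali_from, x$ali_to, x$e_value,
              sum(!is.na(x$state_map))))
  invisible(x)
}

#' Construct an amino acid substitution record
#'
#' @param protein_id protein identifier.
#' @param position 1-based residue position.
#' @param wild_type,mutant single amino-acid letters; must differ.
#' @return an object of class `Substitution`.
#' @export
substitution <- function(protein_id, position, wild_type, mutant) {
  position <- as.integer(position)
  if (is.na(position) || position < 1L)
    stop("position must be a positive integer")
  for (aa in c(wild_type, mutant))
    if (!aa %in% AMINO_ACIDS)
      stop("'", aa, "' is not one of the 20 standard amino acids")
  if (wild_type == mutant)
    stop("wild-type and mutant residues must differ")
  structure(list(protein_id = as.character(protein_id), position = position,
                 wild_type = wild_type, mutant = mutant),
            class = "Substitution")
}

# Expand a run-length map string (e.g. "5M2I3M1D4M") into a per-position
# state map starting at match state `state_from`. M consumes one protein
# residue and one match state, I one residue only, D one state only.
expand_map_string <- function(map_string, n_positions, state_from = 1L) {
  ops <- regmatches(map_string,
                    gregexpr("\\d+[MID]", map_string, perl = TRUE))[[1L]]
  if (!length(ops) ||
      nchar(paste(ops, collapse = "")) != nchar(map_string))
    stop("malformed map string '", map_string, "'")
  counts <- as.integer(sub("[MID]$", "", ops))
  kinds <- sub("^\\d+", "", ops)
  state_map <- integer(0)
  state <- as.integer(state_from)
  for (j in seq_along(ops)) {
    if (kinds[[j]] == "M") {
      state_map <- c(state_map, seq.int(state, length.out = counts[[j]]))
      state <- state + counts[[j]]
    } else if (kinds[[j]] == "I") {
      state_map <- c(state_map, rep(NA_integer_, counts[[j]]))
    } else {
      state <- state + counts[[j]]
    }
  }
  if (length(state_map) != n_positions)
    stop("map string '", map_string, "' covers ", length(state_map),
         " residues but the envelope spans ", n_positions)
  state_map
}

#' Read domain hits from a file
#'
#' Two layouts are accepted. The simplified tab-separated layout has
#' columns `protein_id, model_id, e_value, ali_from, ali_to, map_string`,
#' where `map_string` is a run-length alignment map (`M` = residue aligned
#' to a match state, `I` = inserted residue, `D` = deleted/skipped match
#' state; e.g. `"10M2I5M"`). Alternatively, an `hmmscan --domtblout` table
#' may be given together with a companion map file (`map_path`) whose
#' tab-separated columns are `protein_id, model_id, ali_from, map_string`;
#' the domain's independent e-value and `hmm_from` coordinate are taken
#' from the domtblout row.
#'
#' @param path hits file in either layout.
#' @param format `"auto"` (default; domtblout is recognised by its `#`
#'   comment header or column count), `"simple"` or `"domtblout"`.
#' @param map_path companion alignment-map file, required for domtblout.
#' @return a list of [domain_hit()] objects.
#' @export
read_domain_hits <- function(path, format = c("auto", "simple", "domtblout"),
                             map_path = NULL) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (format == "auto") {
    nf <- if (length(body)) length(strsplit(trimws(body[[1L]]),
                                            "[ \t]+")[[1L]]) else 6L
    format <- if (any(grepl("^#", lines)) || nf >= 22L) "domtblout" else "simple"
  }
  if (format == "simple") {
    hits <- vector("list", length(body))
    keys <- character(length(body))
    for (r in seq_along(body)) {
      f <- strsplit(body[[r]], "\t", fixed = TRUE)[[1L]]
      if (length(f) != 6L)
        stop("row ", r, ": expected 6 tab-separated fields, found ",
             length(f))
      af <- suppressWarnings(as.integer(f[[4L]]))
      at <- suppressWarnings(as.integer(f[[5L]]))
      ev <- suppressWarnings(as.numeric(f[[3L]]))
      if (is.na(af) || is.na(at) || is.na(ev))
        stop("row ", r, ": unparsable coordinates or e-value")
      if (af > at)
        stop("row ", r, ": ali_from > ali_to")
      sm <- expand_map_string(f[[6L]], at - af + 1L)
      hits[[r]] <- domain_hit(f[[1L]], f[[2L]], ev, af, at, sm)
      keys[[r]] <- paste(f[[1L]], f[[2L]], af, at, sep = "\r")
    }
    if (anyDuplicated(keys))
      stop("duplicate (protein, model, envelope) rows: ",
           paste(which(duplicated(keys)), collapse = ", "))
    return(hits)
  }
  # domtblout: standard hmmscan per-domain table (target = model).
  if (is.null(map_path))
    stop("domtblout input needs a companion alignment-map file; ",
         "supply map_path with columns protein_id, model_id, ali_from, ",
         "map_string")
  maps <- utils::read.table(map_path, sep = "\t", header = FALSE,
                            col.names = c("protein_id", "model_id",
                                          "ali_from", "map_string"),
                            colClasses = c("character", "character",
                                           "integer", "character"))
  map_key <- paste(maps$protein_id, maps$model_id, maps$ali_from,
                   sep = "\r")
  hits <- vector("list", length(body))
  keys <- character(length(body))
  for (r in seq_along(body)) {
    f <- strsplit(trimws(body[[r]]), "[ \t]+")[[1L]]
    if (length(f) < 22L)
      stop("row ", r, ": domtblout line has fewer than 22 fields")
    model_id <- if (f[[2L]] != "-") f[[2L]] else f[[1L]]
    protein_id <- f[[4L]]
    ev <- suppressWarnings(as.numeric(f[[13L]]))  # independent e-value
    hmm_from <- suppressWarnings(as.integer(f[[16L]]))
    af <- suppressWarnings(as.integer(f[[18L]]))
    at <- suppressWarnings(as.integer(f[[19L]]))
    if (anyNA(c(ev, hmm_from, af, at)))
      stop("row ", r, ": unparsable coordinates or e-value")
    k <- match(paste(protein_id, model_id, af, sep = "\r"), map_key)
    if (is.na(k))
      stop("row ", r, ": no alignment map for (", protein_id, ", ",
           model_id, ", ", af, "); supply it in the map file")
    sm <- expand_map_string(maps$map_string[[k]], at - af + 1L,
                            state_from = hmm_from)
    hits[[r]] <- domain_hit(protein_id, model_id, ev, af, at, sm)
    keys[[r]] <- paste(protein_id, model_id, af, at, sep = "\r")
  }
  if (anyDuplicated(keys))
    stop("duplicate (protein, model, envelope) rows: ",
         paste(which(duplicated(keys)), collapse = ", "))
  hits
}

#' Write domain hits in the simplified tab-separated layout
#'
#' @param hits list of [domain_hit()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_hits <- function(hits, path) {
  rows <- vapply(hits, function(h) {
    sm <- h$state_map
    kinds <- ifelse(is.na(sm), "I", "M")
    # re-insert D runs where consecutive match states jump
    toks <- character(0)
    prev_state <- 0L  # so a first match state > 1 emits a leading D run
    run_kind <- ""; run_len <- 0L
    flush <- function() if (run_len > 0L)
      toks <<- c(toks, paste0(run_len, run_kind))
    for (j in seq_along(sm)) {
      if (!is.na(sm[[j]]) && sm[[j]] > prev_state + 1L) {
        flush(); run_len <- 0L
        toks <- c(toks, paste0(sm[[j]] - prev_state - 1L, "D"))
      }
      if (kinds[[j]] == run_kind) run_len <- run_len + 1L
      else { flush(); run_kind <- kinds[[j]]; run_len <- 1L }
      if (!is.na(sm[[j]])) prev_state <- sm[[j]]
    }
    flush()
    paste(h$protein_id, h$model_id, format(h$e_value),
          h$ali_from, h$ali_to, paste(toks, collapse = ""), sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Filter domain hits by significance
#'
#' Retains hits whose e-value is at or below the threshold (inclusive
#' boundary), preserving input order.
#'
#' @param hits list of [domain_hit()] objects.
#' @param e_threshold significance threshold; default 0.01.
#' @return the significant subset of `hits`.
#' @export
significant_hits <- function(hits, e_threshold = 0.01) {
  stopifnot(e_threshold > 0)
  hits[vapply(hits, function(h) h$e_value <= e_threshold, logical(1))]
}

#' Resolve a protein position to a match state of a hit
#'
#' @param hit a [domain_hit()] object.
#' @param position 1-based protein residue position.
#' @return the 1-based match-state index, or `NA` when the position lies
#'   outside the hit's envelope or falls on an insert state.
#' @export
resolve_match_state <- function(hit, position) {
  stopifnot(inherits(hit, "DomainHit"))
  position <- as.integer(position)
  if (is.na(position) || position < hit$ali_from || position > hit$ali_to)
    return(NA_integer_)
  hit$state_map[[position - hit$ali_from + 1L]]
}

#' Enumerate candidate models for a substitution
#'
#' For each hit on the substitution's protein that covers its position at
#' a match state, looks the model up in the library and returns the
#' (model, match-state) pair. Hits whose model is absent from the library
#' are skipped with a warning.
#'
#' @param sub a [substitution()] record.
#' @param hits list of [domain_hit()] objects, already significance
#'   filtered (or filter here via `e_threshold`).
#' @param library named list of [profile_hmm()] objects keyed by model_id.
#' @param e_threshold optional significance filter applied before matching.
#' @return list of candidates, each a list with `model`, `state_index`,
#'   `e_value`.
#' @export
candidate_models <- function(sub, hits, library, e_threshold = NULL) {
  stopifnot(inherits(sub, "Substitution"))
  if (!is.null(e_threshold))
    hits <- significant_hits(hits, e_threshold)
  out <- list()
  for (h in hits) {
    if (h$protein_id != sub$protein_id) next
    st <- resolve_match_state(h, sub$position)
    if (is.na(st)) next
    m <- library[[h$model_id]]
    if (is.null(m)) {
      warning("model '", h$model_id, "' not found in library; hit skipped")
      next
    }
    if (st > m$length)
      stop("state ", st, " exceeds model '", h$model_id, "' length ",
           m$length)
    out[[length(out) + 1L]] <- list(model = m, state_index = st,
                                    e_value = h$e_value)
  }
  out
}

#' Represent an ab initio full-protein model as a domain hit
#'
#' A protein-specific model built from a homolog alignment spans the whole
#' sequence with the identity residue-to-state map, so it can enter the
#' same candidate ranking as library domain hits.
#'
#' @param protein_id protein identifier.
#' @param model a [profile_hmm()] object with `source = "ab_initio"`.
#' @param e_value nominal e-value for the self-hit (default 0).
#' @return a [domain_hit()] covering positions `1..model$length` with the
#'   identity map.
#' @export
ab_initio_hit <- function(protein_id, model, e_value = 0) {
  stopifnot(inherits(model, "ProfileHMM"))
  domain_hit(protein_id, model$model_id, e_value, 1L, model$length,
             seq_len(model$length))
}
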