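#' @keywords internal
"_PACKAGE"

# Canonical 20-letter amino acid alphabet in HMMER's default order.
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

MODEL_SOURCES <- c("superfamily", "pfam_a", "pfam_b", "ab_initio")

#' Construct a profile HMM object
#'
#' A `ProfileHMM` holds the per-node match-state emission probabilities of a
#' profile hidden Markov model over the 20 standard amino acids, together
#' with the optional background composition (`COMPO` line) and per-node
#' alignment-column map annotation. Only match states are represented:
#' insert emissions and state transitions are irrelevant to match-state
#' interrogation and are discarded at parse time.
#'
#' @param model_id accession or name of the model.
#' @param match_emissions numeric matrix, one row per match state, 20
#'   columns of emission probabilities. Columns may be named by residue;
#'   unnamed matrices are assumed to follow `alphabet`.
#' @param alphabet ordered amino-acid letters (default HMMER order).
#' @param source one of `"superfamily"`, `"pfam_a"`, `"pfam_b"`,
#'   `"ab_initio"`; identifies the model library for tie-breaking.
#' @param compo optional 20-vector of background probabilities.
#' @param map_annotation optional integer vector of alignment-column
#'   indices (the `MAP` field), one per match state.
#' @param name optional model name when `model_id` carries the accession.
#' @return an object of class `ProfileHMM`.
#' @export
profile_hmm <- function(model_id, match_emissions,
                        alphabet = AMINO_ACIDS,
                        source = "ab_initio",
                        compo = NULL, map_annotation = NULL,
                        name = NULL) {
  source <- match.arg(source, MODEL_SOURCES)
  if (!is.matrix(match_emissions) || ncol(match_emissions) != 20L)
    stop("match_emissions must be a matrix with 20 columns")
  if (nrow(match_emissions) < 1L)
    stop("a profile HMM needs at least one match state")
  if (length(alphabet) != 20L || anyDuplicated(alphabet))
    stop("alphabet must be 20 distinct amino-acid letters")
  if (is.null(colnames(match_emissions)))
    colnames(match_emissions) <- alphabet
  rs <- rowSums(match_emissions)
  if (any(abs(rs - 1) > 1e-6))
    stop("match emission rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  if (any(match_emissions < 0) || any(match_emissions > 1))
    stop("emission probabilities must lie in [0, 1]")
  if (!is.null(compo)) {
    compo <- as.numeric(compo)
    if (length(compo) != 20L)
      stop("compo must have 20 entries")
    names(compo) <- alphabet
  }
  if (!is.null(map_annotation) &&
      length(map_annotation) != nrow(match_emissions))
    stop("map_annotation length must equal the number of match states")
  structure(list(
    model_id = as.character(model_id),
    name = if (is.null(name)) as.character(model_id) else as.character(name),
    source = source,
    length = nrow(match_emissions),
    alphabet = as.character(alphabet),
    match_emissions = match_emissions,
    compo = compo,
    map_annotation = map_annotation
  ), class = "ProfileHMM")
}

#' @export
print.ProfileHMM <- function(x, ...) {
  cat("ProfileHMM", x$model_id, sprintf("(%s)", x$source),
      "-", x$length, "match states\n")
  cat("  COMPO:", if (is.null(x$compo)) "absent" else "present",
      " MAP:", if (is.null(x$map_annotation)) "absent" else "present", "\n")
  invisible(x)
}

# Guess the library a model belongs to from its accession/name.
infer_model_source <- function(acc, name) {
  id <- if (!is.null(acc) && nzchar(acc)) acc else name
  if (grepl("^PF\\d", id)) return("pfam_a")
  if (grepl("^PB\\d", id)) return("pfam_b")
  if (grepl("^(SSF|\\d+$)", id)) return("superfamily")
  "ab_initio"
}

# Convert a HMMER3 stored score to a probability: scores are negative
# natural logs; "*" encodes probability exactly 0.
score_to_prob <- function(tok) {
  ifelse(tok == "*", 0, exp(-suppressWarnings(as.numeric(tok))))
}

prob_to_score <- function(p) {
  # 9 decimals keeps a write/read/write cycle stable to ~1e-9; HMMER's
  # own 5-decimal output parses the same way
  ifelse(p == 0, "*", sprintf("%.9f", -log(p)))
}

#' Read a HMMER3 ASCII profile HMM file
#'
#' Parses the `HMMER3/f` ASCII dialect (other HMMER3 minor versions are
#' accepted when the structural fields parse). Stored emission scores are
#' negative natural logarithms of probabilities and are converted with
#' `exp(-s)`; the `*` token maps to probability exactly 0. Only match
#' emission rows, the `COMPO` line, `LENG`, `NAME`, `ACC` and the `MAP`
#' column are retained.
#'
#' @param path path to a HMMER3 ASCII file containing one amino-acid model.
#' @param source model library; `"auto"` (default) infers it from the
#'   accession (`PF` = Pfam-A, `PB` = Pfam-B, `SSF`/numeric = SUPERFAMILY,
#'   otherwise ab initio).
#' @return a [profile_hmm()] object.
#' @export
read_profile <- function(path, source = "auto") {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^HMMER3", lines[[1L]]))
    stop("line 1: not a HMMER3 ASCII file (missing HMMER3 format tag)")

  name <- NULL; acc <- NULL; leng <- NULL; alph <- NULL
  i <- 2L
  while (i <= length(lines) && !grepl("^HMM\\s", lines[[i]])) {
    key <- sub("^(\\S+).*", "\\1", lines[[i]])
    val <- trimws(sub("^\\S+\\s*", "", lines[[i]]))
    if (key == "NAME") name <- val
    if (key == "ACC")  acc  <- val
    if (key == "LENG") leng <- suppressWarnings(as.integer(val))
    if (key == "ALPH") alph <- tolower(val)
    i <- i + 1L
  }
  if (i > length(lines))
    stop("no HMM alphabet line found")
  if (is.null(leng) || is.na(leng) || leng < 1L)
    stop("missing or invalid LENG header")
  if (!identical(alph, "amino"))
    stop("alphabet is not amino (ALPH ", if (is.null(alph)) "absent" else alph, ")")

  alphabet <- strsplit(trimws(sub("^HMM\\s+", "", lines[[i]])), "\\s+")[[1L]]
  if (length(alphabet) != 20L)
    stop("line ", i, ": HMM header must list 20 residues, found ",
         length(alphabet))
  i <- i + 2L  # skip the transition-name header line

  compo <- NULL
  if (i <= length(lines) && grepl("^\\s*COMPO\\s", lines[[i]])) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]][-1L]
    if (length(tok) < 20L)
      stop("line ", i, ": COMPO line has fewer than 20 values")
    compo <- score_to_prob(tok[1:20])
    if (anyNA(compo))
      stop("line ", i, ": unparsable numeric token on COMPO line")
    i <- i + 3L  # skip node-0 insert emission and transition lines
  }

  emis <- matrix(NA_real_, nrow = leng, ncol = 20L,
                 dimnames = list(NULL, alphabet))
  map_ann <- rep(NA_integer_, leng)
  node <- 0L
  while (i <= length(lines) && !grepl("^//", lines[[i]])) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]]
    if (length(tok) < 21L)
      stop("line ", i, ": match emission line has fewer than 21 fields")
    node <- node + 1L
    if (node > leng)
      stop("line ", i, ": more match-state rows than LENG = ", leng)
    idx <- suppressWarnings(as.integer(tok[[1L]]))
    if (is.na(idx) || idx != node)
      stop("line ", i, ": expected node index ", node, ", found ", tok[[1L]])
    p <- score_to_prob(tok[2:21])
    if (anyNA(p))
      stop("line ", i, ": unparsable numeric token in match emissions")
    emis[node, ] <- p
    if (length(tok) >= 22L && grepl("^\\d+$", tok[[22L]]))
      map_ann[node] <- as.integer(tok[[22L]])
    i <- i + 3L  # skip insert emission and transition lines
  }
  if (node != leng)
    stop("parsed ", node, " match-state rows but LENG = ", leng)

  if (source == "auto")
    source <- infer_model_source(acc, name)
  rs <- rowSums(emis)
  if (any(abs(rs - 1) > 1e-4))
    stop("match emission rows do not sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  emis <- emis / rs  # absorb format rounding so invariants hold exactly

  profile_hmm(
    model_id = if (!is.null(acc) && nzchar(acc)) acc else name,
    match_emissions = emis, alphabet = alphabet, source = source,
    compo = compo,
    map_annotation = if (all(is.na(map_ann))) NULL else map_ann,
    name = name
  )
}

#' Write a profile HMM in HMMER3 ASCII format
#'
#' Emits a minimal but valid `HMMER3/f` file that [read_profile()] (and
#' HMMER itself, structurally) accepts. Probabilities are stored as
#' negative natural logs at 5 decimal places; probability 0 is written as
#' `*`. Insert emissions are written as the uniform distribution and
#' transitions as flat placeholders, since scoring never consumes them.
#'
#' @param model a [profile_hmm()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(model, path) {
  stopifnot(inherits(model, "ProfileHMM"))
  rs <- rowSums(model$match_emissions)
  if (any(abs(rs - 1) > 1e-6))
    stop("refusing to write non-normalized emission rows")
  unif <- sprintf("%.5f", log(20))
  trans <- paste(rep(sprintf("%.5f", log(2)), 7L), collapse = "  ")
  out <- c(
    "HMMER3/f [hmmvar | profile writer]",
    paste("NAME ", model$name),
    paste("ACC  ", model$model_id),
    paste("LENG ", model$length),
    "ALPH  amino",
    paste("HMM  ", paste(model$alphabet, collapse = "        ")),
    paste(" ", paste(c("m->m", "m->i", "m->d", "i->m", "i->i",
                       "d->m", "d->d"), collapse = "     "))
  )
  if (!is.null(model$compo)) {
    out <- c(out,
      paste("  COMPO  ", paste(prob_to_score(model$compo), collapse = "  ")),
      paste("          ", paste(rep(unif, 20L), collapse = "  ")),
      paste("          ", trans))
  }
  for (k in seq_len(model$length)) {
    map_tok <- if (!is.null(model$map_annotation) &&
                   !is.na(model$map_annotation[[k]]))
      as.character(model$map_annotation[[k]]) else "-"
    out <- c(out,
      paste0(sprintf("%7d  ", k),
             paste(prob_to_score(model$match_emissions[k, ]), collapse = "  "),
             "  ", map_tok, " - - - -"),
      paste("          ", paste(rep(unif, 20L), collapse = "  ")),
      paste("          ", trans))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Look up a match-state emission probability
#'
#' @param model a [profile_hmm()] object.
#' @param state_index 1-based match-state index.
#' @param residue single amino-acid letter from the model's alphabet.
#' @return the emission probability of `residue` at that match state.
#' @export
emission_probability <- function(model, state_index, residue) {
  stopifnot(inherits(model, "ProfileHMM"))
  if (!is.numeric(state_index) || length(state_index) != 1L ||
      state_index < 1L || state_index > model$length ||
      state_index != round(state_index))
    stop("state_index out of range [1, ", model$length, "]: ", state_index)
  col <- match(residue, model$alphabet)
  if (is.na(col))
    stop("residue '", residue, "' is not in the 20-letter alphabet")
  unname(model$match_emissions[as.integer(state_index), col])
}

#' Resolve the background amino acid composition for a model
#'
#' Resolution order: a user-supplied composition file if given, else the
#' model's `COMPO` line, else the uniform distribution 1/20. A user file
#' holds 20 whitespace-separated `letter probability` pairs (any order);
#' this is where a SwissProt/TrEMBL-style global composition is supplied.
#'
#' @param model a [profile_hmm()] object.
#' @param override optional path to a composition file, or a named
#'   20-vector of probabilities.
#' @return a list with `probabilities` (20-vector in the model's alphabet
#'   order, summing to 1) and `provenance` (`"user_file"`, `"compo_line"`
#'   or `"uniform"`), of class `BackgroundComposition`.
#' @export
background_composition <- function(model, override = NULL) {
  stopifnot(inherits(model, "ProfileHMM"))
  if (!is.null(override)) {
    if (is.character(override) && length(override) == 1L) {
      tok <- scan(override, what = character(), quiet = TRUE)
      if (length(tok) != 40L)
        stop("composition file must hold 20 letter/probability pairs")
      letters_in <- tok[seq(1L, 39L, by = 2L)]
      probs_in <- suppressWarnings(as.numeric(tok[seq(2L, 40L, by = 2L)]))
      if (anyNA(probs_in))
        stop("unparsable probability in composition file")
      names(probs_in) <- letters_in
      override <- probs_in
    }
    if (length(override) != 20L || is.null(names(override)))
      stop("composition override must be a named 20-vector")
    if (abs(sum(override) - 1) > 1e-4)
      stop("composition does not sum to 1 (sum = ", format(sum(override)), ")")
    p <- override[model$alphabet]
    if (anyNA(p))
      stop("composition is missing letters of the model alphabet")
    p <- p / sum(p)
    return(structure(list(probabilities = p, provenance = "user_file"),
                     class = "BackgroundComposition"))
  }
  if (!is.null(model$compo)) {
    p <- model$compo / sum(model$compo)
    return(structure(list(probabilities = p, provenance = "compo_line"),
                     class = "BackgroundComposition"))
  }
  p <- stats::setNames(rep(1 / 20, 20L), model$alphabet)
  structure(list(probabilities = p, provenance = "uniform"),
            class = "BackgroundComposition")
}
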