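# Synthetic fixtures: profile HMMs with controlled conservation, domain
# hits, and labeled benchmark bundles with a planted effect, so the whole
# pipeline is exercisable without any external database. The generator
# emulates the shape of real inputs (HMMER3 models, hit tables, labeled
# substitution lists), not the biology of real protein families.

#' Generate a synthetic profile HMM with controlled conservation
#'
#' Every match state mixes a point mass on a randomly chosen (seeded)
#' consensus residue with the uniform distribution:
#' `p = conservation * point_mass + (1 - conservation) / 20`. At
#' `conservation = 1` each state's information content against a uniform
#' background is `ln(20)` nats; at 0 it is exactly 0.
#'
#' @param length number of match states.
#' @param conservation mixing weight in \[0, 1\].
#' @param seed integer seed; the same seed reproduces the model exactly.
#' @param model_id model identifier (default derived from the seed).
#' @param source model library tag (default `"pfam_a"`).
#' @return a [profile_hmm()] object.
#' @export
synth_profile <- function(length, conservation, seed,
                          model_id = sprintf("SYN%05d", seed %% 100000L),
                          source = "pfam_a") {
  if (length < 1L) stop("length must be >= 1")
  if (conservation < 0 || conservation > 1)
    stop("conservation must lie in [0, 1]")
  set.seed(seed)
  consensus <- sample.int(20L, length, replace = TRUE)
  emis <- matrix((1 - conservation) / 20, nrow = length, ncol = 20L,
                 dimnames = list(NULL, AMINO_ACIDS))
  emis[cbind(seq_len(length), consensus)] <-
    emis[cbind(seq_len(length), consensus)] + conservation
  m <- profile_hmm(model_id, emis, source = source)
  m$consensus <- AMINO_ACIDS[consensus]
  m
}

#' Build a profile from a multiple sequence alignment
#'
#' A deliberately simple pseudo-count profile builder standing in for a
#' full HMM construction: alignment columns whose gap fraction is at most
#' `gap_rule` become match states, and emissions are
#' `(count + pseudocount) / (n_observed + 20 * pseudocount)` per column.
#' Dirichlet mixture priors are not used, so emission estimates are
#' cruder than those of real alignment-derived models.
#'
#' @param msa character vector of equal-length aligned sequences
#'   (residues plus `-`/`.` gaps).
#' @param gap_rule maximum gap fraction for a match column (default 0.5).
#' @param pseudocount additive pseudo-count (default 1).
#' @param model_id model identifier.
#' @return a [profile_hmm()] with `source = "ab_initio"`;
#'   `map_annotation` records each match state's source column.
#' @export
profile_from_msa <- function(msa, gap_rule = 0.5, pseudocount = 1,
                             model_id = "msa_profile") {
  if (!length(msa)) stop("empty alignment")
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: sequence lengths ",
         paste(unique(widths), collapse = ", "))
  rows <- strsplit(toupper(msa), "", fixed = TRUE)
  ncol_aln <- widths[[1L]]
  emis <- NULL; map_ann <- integer(0)
  for (j in seq_len(ncol_aln)) {
    col <- vapply(rows, `[[`, character(1), j)
    is_gap <- col %in% c("-", ".")
    if (mean(is_gap) > gap_rule) next
    obs <- col[!is_gap]
    bad <- setdiff(obs, AMINO_ACIDS)
    if (length(bad))
      stop("non-standard residue(s) in column ", j, ": ",
           paste(unique(bad), collapse = ", "))
    counts <- table(factor(obs, levels = AMINO_ACIDS))
    p <- (as.numeric(counts) + pseudocount) /
      (length(obs) + 20 * pseudocount)
    emis <- rbind(emis, p)
    map_ann <- c(map_ann, j)
  }
  if (is.null(emis))
    stop("no column satisfies the gap rule; no match states")
  dimnames(emis) <- list(NULL, AMINO_ACIDS)
  profile_hmm(model_id, emis, source = "ab_initio",
              map_annotation = map_ann)
}

#' Generate a labeled synthetic benchmark bundle
#'
#' Creates a library of synthetic models (half highly conserved, half
#' weakly conserved), one full-length protein and identity-mapped domain
#' hit per model, and a labeled substitution table with a planted effect:
#' disease records substitute the consensus residue of a highly conserved
#' state for a low-probability mutant, while neutral records fall on
#' weakly conserved states where every residue is near-equiprobable.
#' The bundle's `planted_effect` is the mean unweighted-score separation
#' between the neutral and disease records, measured by running the full
#' prediction pipeline.
#'
#' @param n_models number of models (>= 2; split between high and low
#'   conservation).
#' @param n_disease,n_neutral number of disease / neutral records.
#' @param conservation_high,conservation_low mixing weights of the two
#'   model classes (defaults 0.99 and 0.1).
#' @param seed integer seed; the same seed reproduces the bundle exactly.
#' @param model_length match states per model (default 50).
#' @return list of class `FixtureBundle`: `models` (named list),
#'   `hits`, `mutations` (data.frame with `label`), `planted_effect`,
#'   `seed`.
#' @export
synth_benchmark <- function(n_models, n_disease, n_neutral,
                            conservation_high = 0.99,
                            conservation_low = 0.1,
                            seed = 1L, model_length = 50L) {
  stopifnot(n_models >= 2L, n_disease >= 1L, n_neutral >= 1L)
  n_high <- ceiling(n_models / 2)
  models <- vector("list", n_models)
  ids <- character(n_models)
  for (k in seq_len(n_models)) {
    cons <- if (k <= n_high) conservation_high else conservation_low
    id <- sprintf("PF9%04d", k)
    models[[k]] <- synth_profile(model_length, cons,
                                 seed = seed * 1000L + k,
                                 model_id = id, source = "pfam_a")
    ids[[k]] <- id
  }
  names(models) <- ids
  hits <- lapply(seq_len(n_models), function(k)
    domain_hit(paste0("prot_", ids[[k]]), ids[[k]], 1e-10,
               1L, model_length, seq_len(model_length)))

  set.seed(seed)
  draw_record <- function(model_k, disease) {
    m <- models[[model_k]]
    pos <- sample.int(model_length, 1L)
    if (disease) {
      wt <- m$consensus[[pos]]
      mut <- sample(setdiff(AMINO_ACIDS, wt), 1L)
    } else {
      wt <- sample(AMINO_ACIDS, 1L)
      mut <- sample(setdiff(AMINO_ACIDS, wt), 1L)
    }
    data.frame(protein_id = paste0("prot_", ids[[model_k]]),
               position = pos, wild_type = wt, mutant = mut,
               label = if (disease) "disease" else "neutral",
               stringsAsFactors = FALSE)
  }
  disease_rows <- lapply(sample(seq_len(n_high), n_disease,
                                replace = TRUE),
                         draw_record, disease = TRUE)
  neutral_rows <- lapply(sample(seq.int(n_high + 1L, n_models),
                                n_neutral, replace = TRUE),
                         draw_record, disease = FALSE)
  mutations <- do.call(rbind, c(disease_rows, neutral_rows))
  rownames(mutations) <- NULL

  preds <- predict_substitutions(mutations, hits, models)
  planted <- mean(preds$score[mutations$label == "neutral"]) -
    mean(preds$score[mutations$label == "disease"])

  structure(list(models = models, hits = hits, mutations = mutations,
                 planted_effect = planted, seed = seed),
            class = "FixtureBundle")
}

#' @export
print.FixtureBundle <- function(x, ...) {
  cat(sprintf(paste0("FixtureBundle: %d models, %d mutations ",
                     "(planted effect %.2f nats, seed %d)\n"),
              length(x$models), nrow(x$mutations), x$planted_effect,
              x$seed))
  invisible(x)
}

#' Write / read a fixture bundle
#'
#' Writes the bundle in the formats every other entry point consumes:
#' `models/<id>.hmm` (HMMER3 ASCII), `hits.tsv` (simplified hit layout)
#' and `mutations.tsv` (labeled substitution table).
#'
#' @param bundle a `FixtureBundle`.
#' @param dir output directory (created if needed).
#' @return `dir` (write) or a list with `models`, `hits`, `mutations`
#'   (read).
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "FixtureBundle"))
  dir.create(file.path(dir, "models"), recursive = TRUE,
             showWarnings = FALSE)
  for (m in bundle$models)
    write_profile(m, file.path(dir, "models",
                               paste0(m$model_id, ".hmm")))
  write_domain_hits(bundle$hits, file.path(dir, "hits.tsv"))
  utils::write.table(bundle$mutations, file.path(dir, "mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  paths <- list.files(file.path(dir, "models"), pattern = "\\.hmm$",
                      full.names = TRUE)
  models <- lapply(paths, read_profile)
  names(models) <- vapply(models, `[[`, character(1), "model_id")
  list(models = models,
       hits = read_domain_hits(file.path(dir, "hits.tsv"),
                               format = "simple"),
       mutations = read_labeled_substitutions(
         file.path(dir, "mutations.tsv")))
}
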