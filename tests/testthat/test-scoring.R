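test_that("unweighted score matches hand arithmetic and sign convention", {
  expect_equal(unweighted_score(0.3, 0.3), 0)
  expect_equal(unweighted_score(0.8, 0.2), log(0.25), tolerance = 1e-12)
  # a favorable substitution (mutant more likely) scores positive
  expect_equal(unweighted_score(0.2, 0.8), log(4), tolerance = 1e-12)
  # odds strategy shares the zero point and sign
  expect_equal(unweighted_score(0.3, 0.3, formula = "odds"), 0)
  expect_gt(unweighted_score(0.2, 0.8, formula = "odds"), 0)
  expect_lt(unweighted_score(0.8, 0.2, formula = "odds"), 0)
})

test_that("zero probabilities are floored with a warning, not an error", {
  expect_warning(s <- unweighted_score(0.5, 0), "floored")
  expect_true(is.finite(s))
  expect_equal(s, log(1e-10 / 0.5), tolerance = 1e-12)
  expect_warning(s2 <- unweighted_score(0, 0.5), "floored")
  expect_equal(s2, log(0.5 / 1e-10), tolerance = 1e-12)
})

test_that("weighted score modulates by ln(Wn/Wd) and reduces when equal", {
  expect_equal(weighted_score(0.5, 0.5, w_d = 10, w_n = 5), log(0.5),
               tolerance = 1e-12)
  expect_equal(weighted_score(0.8, 0.2, w_d = 3, w_n = 3),
               unweighted_score(0.8, 0.2), tolerance = 1e-12)
  expect_error(weighted_score(0.5, 0.5, w_d = 0, w_n = 1), "positive")
  # monotone: increasing W_d never increases the score
  s <- vapply(c(1, 2, 5, 20), function(wd)
    weighted_score(0.4, 0.3, wd, 2), numeric(1))
  expect_true(all(diff(s) < 0))
})

test_that("score strategy contracts hold on random draws", {
  set.seed(303)
  n <- 2000
  pw <- stats::runif(n, 1e-6, 1 - 1e-6)
  pm <- stats::runif(n, 1e-6, 1 - 1e-6)
  wd <- stats::rexp(n) + 0.1
  wn <- stats::rexp(n) + 0.1
  for (i in seq_len(n)) {
    for (fm in c("ratio", "odds")) {
      s <- unweighted_score(pw[i], pm[i], fm)
      # antisymmetry under argument swap
      expect_equal(unweighted_score(pm[i], pw[i], fm), -s,
                   tolerance = 1e-9)
      # sign matches the probability comparison
      expect_identical(s > 0, pm[i] > pw[i])
    }
    # weighted - unweighted is the constant ln(Wn/Wd) for the ratio pair
    expect_equal(
      weighted_score(pw[i], pm[i], wd[i], wn[i]) -
        unweighted_score(pw[i], pm[i]),
      log(wn[i] / wd[i]), tolerance = 1e-9)
  }
})

test_that("classification is strict-below-threshold with ties tolerated", {
  expect_identical(classify(-3.1, default_threshold("unweighted")),
                   "damaging")
  expect_identical(classify(-3.0, -3.0), "tolerated")
  expect_identical(classify(-1.5, default_threshold("weighted")),
                   "tolerated")
  expect_identical(classify(-1.51, -1.5), "damaging")
  expect_identical(classify(0, -3.0), "tolerated")
  expect_identical(classify(0, -1.5), "tolerated")
})

test_that("predict runs the full pipeline on a constructed fixture", {
  peaked <- peaked_model(10, "A", peak = 1 - 19e-10, model_id = "PK",
                         source = "pfam_a")
  lib <- list(PK = peaked)
  hits <- list(domain_hit("p", "PK", 1e-8, 1, 10, 1:10))
  sub <- substitution("p", 4, "A", "W")
  pred <- predict_substitution(sub, hits, lib)
  expect_identical(pred$call, "damaging")
  expect_lt(pred$score, -15)
  expect_identical(pred$model_id, "PK")
  expect_identical(pred$state_index, 4L)
  # deterministic
  expect_identical(predict_substitution(sub, hits, lib), pred)
})

test_that("no covering candidate yields no_prediction", {
  lib <- list(PK = peaked_model(10, "A", model_id = "PK"))
  hits <- list(domain_hit("p", "PK", 1e-8, 1, 10, 1:10))
  out <- predict_substitution(substitution("p", 50, "A", "C"), hits, lib)
  expect_identical(out$call, "no_prediction")
  expect_true(is.na(out$score))
  # insignificant hit -> no candidate
  weak <- list(domain_hit("p", "PK", 0.5, 1, 10, 1:10))
  out2 <- predict_substitution(substitution("p", 4, "A", "C"), weak, lib)
  expect_identical(out2$call, "no_prediction")
})

test_that("weighted mode is restricted to library domains", {
  ab <- uniform_model(10, "abinit_p", source = "ab_initio")
  lib <- list(abinit_p = ab)
  hits <- list(ab_initio_hit("p", ab))
  wt <- weight_table(data.frame(model_id = "abinit_p",
                                disease_count = 5L, neutral_count = 1L))
  sub <- substitution("p", 4, "A", "C")
  # unweighted mode scores against the ab initio model
  unw <- predict_substitution(sub, hits, lib)
  expect_identical(unw$model_id, "abinit_p")
  expect_equal(unw$score, 0)
  # weighted mode never falls back to it
  w <- predict_substitution(sub, hits, lib, weights = wt)
  expect_identical(w$call, "no_prediction")
})

test_that("the most informative model wins and weights shift its score", {
  peaked <- peaked_model(10, "L", peak = 0.95, model_id = "PKD")
  unif <- uniform_model(10, "UNF", source = "pfam_a")
  lib <- list(PKD = peaked, UNF = unif)
  hits <- list(domain_hit("p", "PKD", 1e-8, 1, 10, 1:10),
               domain_hit("p", "UNF", 1e-8, 1, 10, 1:10))
  sub <- substitution("p", 6, "L", "V")
  pred <- predict_substitution(sub, hits, lib)
  expect_identical(pred$model_id, "PKD")
  wt <- weight_table(data.frame(model_id = "PKD", disease_count = 9L,
                                neutral_count = 4L))
  predw <- predict_substitution(sub, hits, lib, weights = wt)
  expect_equal(predw$score, pred$score + log(5 / 10), tolerance = 1e-12)
})

test_that("end-to-end prediction agrees with the enumeration oracle", {
  set.seed(909)
  for (trial in 1:60) {
    n_models <- sample(2:4, 1)
    lib <- list()
    hits <- list()
    for (k in seq_len(n_models)) {
      id <- sprintf("M%d", k)
      src <- sample(c("superfamily", "pfam_a", "pfam_b"), 1)
      m <- synth_profile(12, stats::runif(1), seed = trial * 100 + k,
                         model_id = id, source = src)
      if (stats::runif(1) < 0.3)
        m$compo <- stats::setNames(random_simplex(), AA)
      lib[[id]] <- m
      from <- sample(1:4, 1)
      sm <- seq_len(12)
      drop <- sample(12, sample(0:3, 1))
      sm[drop] <- NA
      keep <- !is.na(sm)
      sm[keep] <- seq_len(sum(keep))
      hits[[k]] <- domain_hit("prot", id, 10^stats::runif(1, -8, 0),
                              from, from + 11L, sm)
    }
    wt <- weight_table(data.frame(
      model_id = names(lib),
      disease_count = sample(0:10, n_models, replace = TRUE),
      neutral_count = sample(0:10, n_models, replace = TRUE)))
    pos <- sample(1:16, 1)
    wt_res <- sample(AA, 1)
    sub <- substitution("prot", pos, wt_res,
                        sample(setdiff(AA, wt_res), 1))
    for (weights in list(NULL, wt)) {
      got <- suppressWarnings(
        predict_substitution(sub, hits, lib, weights = weights))
      want <- predict_oracle(sub, hits, lib, weights = weights)
      if (is.null(want)) {
        expect_identical(got$call, "no_prediction")
      } else {
        expect_identical(got$model_id, want$model_id)
        expect_identical(got$state_index, want$state)
        expect_equal(got$score, want$score, tolerance = 1e-9)
      }
    }
  }
})

test_that("predict_substitutions carries labels through and batches", {
  b <- synth_benchmark(4, 5, 5, seed = 33)
  preds <- predict_substitutions(b$mutations, b$hits, b$models)
  expect_identical(nrow(preds), 10L)
  expect_identical(preds$label, b$mutations$label)
  expect_true(all(preds$call %in% c("damaging", "tolerated")))
})
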