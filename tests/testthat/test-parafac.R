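test_that("tucker_congruence matches closed forms", {
  expect_equal(tucker_congruence(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(tucker_congruence(c(1, 0), c(0, 1)), 0)
  expect_equal(tucker_congruence(c(1, 1), c(1, 3)), 4 / sqrt(20),
               tolerance = 1e-9)
  expect_error(tucker_congruence(c(0, 0), c(1, 1)),
               class = "fdomlink_undefined_similarity_error")
  expect_error(tucker_congruence(1:3, 1:4), class = "fdomlink_shape_error")
})

test_that("fit_parafac recovers exact low-rank structure", {
  # noiseless rank-1
  g1 <- generate_eem_dataset(n_samples = 5, snr = Inf, seed = 1,
                             components = component_specs_default()[2])
  m1 <- fit_parafac(g1$dataset, 1, n_starts = 2, max_iter = 600, seed = 1)
  expect_gte(m1$explained_variance, 0.9999)

  # noiseless rank-3: loadings recovered after congruence matching
  g3 <- generate_eem_dataset(n_samples = 12, snr = Inf, seed = 2,
                             components = component_specs_default()[c(1, 3, 4)])
  m3 <- fit_parafac(g3$dataset, 3, n_starts = 3, max_iter = 1500, seed = 2)
  expect_true(all(recovery_congruence(m3, g3$truth) >= 0.999))

  # pure (zero-mean) noise: 4 components cannot explain half the variance
  set.seed(3)
  ex <- seq(250, 350, 5); em <- seq(300, 450, 5)
  noise <- lapply(1:10, function(s)
    eem(paste0("n", s), ex, em,
        matrix(rnorm(length(em) * length(ex)), length(em), length(ex))))
  mn <- fit_parafac(eem_dataset(noise), 4, n_starts = 2, max_iter = 300,
                    seed = 3, floor_negatives = FALSE)
  expect_lt(mn$explained_variance, 0.5)

  expect_error(fit_parafac(g1$dataset, 99), class = "fdomlink_rank_error")
})

test_that("ALS loss is monotone and fit is deterministic given seed", {
  g <- generate_eem_dataset(n_samples = 8, snr = 20, seed = 4,
                            ex_nm = seq(250, 350, 5), em_nm = seq(300, 450, 5))
  m <- fit_parafac(g$dataset, 4, n_starts = 1, max_iter = 200, seed = 9)
  expect_true(all(diff(m$loss_trace) <= 1e-10 * m$loss_trace[-length(m$loss_trace)]
                  + 1e-300))
  m2 <- fit_parafac(g$dataset, 4, n_starts = 1, max_iter = 200, seed = 9)
  expect_identical(m$scores, m2$scores)
  expect_identical(m$sse, m2$sse)
})

test_that("loading convention: unit maxima, nonnegative scores", {
  g <- generate_eem_dataset(n_samples = 10, snr = 30, seed = 5)
  m <- fit_parafac(g$dataset, 4, n_starts = 2, max_iter = 500, seed = 5)
  expect_equal(unname(apply(m$ex_loadings, 2, max)), rep(1, 4))
  expect_equal(unname(apply(m$em_loadings, 2, max)), rep(1, 4))
  expect_true(all(m$scores >= 0))
  expect_equal(m$explained_variance, 1 - m$sse / (m$sse / (1 - m$explained_variance)),
               tolerance = 1e-9)
})

test_that("decomposition is invariant to sample order and per-sample scale", {
  g <- generate_eem_dataset(n_samples = 10, snr = Inf, seed = 6)
  m <- fit_parafac(g$dataset, 4, n_starts = 2, max_iter = 800, seed = 6)

  shuf <- g$dataset$eems[c(4, 1, 9, 2, 10, 3, 8, 5, 7, 6)]
  ms <- fit_parafac(eem_dataset(shuf), 4, n_starts = 2, max_iter = 800,
                    seed = 6)
  for (k in 1:4) {
    congs <- vapply(1:4, function(j)
      tucker_congruence(m$em_loadings[, k], ms$em_loadings[, j]), 0)
    expect_gte(max(congs), 0.999)
  }

  # scaling one sample's EEM by 10 changes only that sample's score
  scaled <- g$dataset$eems
  scaled[[3]]$intensity <- scaled[[3]]$intensity * 10
  msc <- fit_parafac(eem_dataset(scaled), 4, n_starts = 2, max_iter = 800,
                     seed = 6)
  for (k in 1:4) {
    congs <- vapply(1:4, function(j)
      tucker_congruence(m$ex_loadings[, k], msc$ex_loadings[, j]), 0)
    expect_gte(max(congs), 0.999)
  }
  expect_equal(unname(msc$scores[3, ]), unname(m$scores[3, ]) * 10,
               tolerance = 1e-3)

  # missing cells: excising 5% of cells still recovers the loadings
  holey <- g$dataset$eems
  set.seed(11)
  for (s in seq_along(holey)) {
    idx <- sample(length(holey[[s]]$intensity),
                  round(0.05 * length(holey[[s]]$intensity)))
    holey[[s]]$intensity[idx] <- NA
  }
  mh <- fit_parafac(eem_dataset(holey), 4, n_starts = 2, max_iter = 800,
                    seed = 6)
  expect_true(all(recovery_congruence(mh, g$truth) >= 0.99))
})

test_that("split_half_validate passes on a clean fixture and fails when built to", {
  g <- generate_eem_dataset(n_samples = 24, snr = Inf, seed = 7)
  rep_ok <- split_half_validate(g$dataset, 4, n_splits = 1, seed = 1,
                                n_starts = 3, max_iter = 2000)
  expect_true(rep_ok$pass)

  expect_false(split_half_validate(g$dataset, 4, n_splits = 1,
                                   threshold = 1.01, seed = 1, n_starts = 1,
                                   max_iter = 50)$pass)

  # halves drawn from disjoint chemical populations cannot replicate
  specs <- component_specs_default()
  gA <- generate_eem_dataset(n_samples = 8, snr = Inf, seed = 8,
                             components = specs[c(1, 2)])
  gB <- generate_eem_dataset(n_samples = 8, snr = Inf, seed = 9,
                             components = specs[c(3, 4)])
  eems <- c(gA$dataset$eems, gB$dataset$eems)
  names(eems) <- NULL
  for (i in seq_along(eems)) eems[[i]]$sample_id <- sprintf("mix%02d", i)
  mixed <- eem_dataset(eems)
  # halves fixed to the two disjoint populations cannot replicate
  reps <- split_half_validate(mixed, 2, halves = list(1:8, 9:16), seed = 3,
                              n_starts = 2, max_iter = 500)
  expect_false(reps$pass)

  expect_error(split_half_validate(g$dataset, 99),
               class = "fdomlink_validation_error")
})

test_that("fmax and percent composition follow their conventions", {
  g <- generate_eem_dataset(n_samples = 10, snr = Inf, seed = 10)
  m <- fit_parafac(g$dataset, 4, n_starts = 2, max_iter = 800, seed = 10)
  fm <- fmax_scores(m)
  expect_equal(fm, m$scores)    # unit-max convention: Fmax == scores

  # rescaling a loading column with compensating score leaves Fmax unchanged
  m2 <- m
  m2$ex_loadings[, 1] <- m2$ex_loadings[, 1] * 0.5
  m2$scores[, 1] <- m2$scores[, 1] * 2
  expect_equal(fmax_scores(m2)[, 1], fm[, 1], tolerance = 1e-12)

  # Fmax proportional to the generator's true mixing weights
  perm <- vapply(1:4, function(j) which.max(vapply(1:4, function(k)
    tucker_congruence(m$em_loadings[, k], g$truth$em_loadings[, j]), 0)), 0L)
  for (j in 1:4) {
    expect_gte(cor(fm[, perm[j]], g$truth$weights[, j]), 0.99)
  }

  expect_equal(percent_composition(matrix(c(1, 1, 1, 1), 1)),
               matrix(25, 1, 4))
  expect_equal(percent_composition(matrix(c(3, 1, 0, 0), 1)),
               matrix(c(75, 25, 0, 0), 1))
  set.seed(2)
  r <- matrix(rexp(60), 10)
  expect_equal(unname(rowSums(percent_composition(r))), rep(100, 10),
               tolerance = 1e-9)
  expect_error(percent_composition(rbind(r, 0)),
               class = "fdomlink_undefined_composition_error")
})

test_that("component classification follows the peak rules", {
  cases <- list(list(275, 304, "tyrosine-like"),
                list(280, 340, "tryptophan-like"),
                list(250, 450, "terrestrial humic-like"),
                list(310, 410, "microbial humic-like"))
  g <- generate_eem_dataset(n_samples = 8, snr = Inf, seed = 12)
  m <- fit_parafac(g$dataset, 4, n_starts = 2, max_iter = 800, seed = 12)
  cls <- classify_components(m)
  expect_setequal(cls$label, c("tyrosine-like", "tryptophan-like",
                               "terrestrial humic-like",
                               "microbial humic-like"))
  for (cs in cases) {
    expect_identical(fdomlink:::classify_peak(cs[[1]], cs[[2]]), cs[[3]])
  }
})

test_that("match_reference finds its own loadings and rejects junk", {
  g <- generate_eem_dataset(n_samples = 8, snr = Inf, seed = 13)
  m <- fit_parafac(g$dataset, 4, n_starts = 2, max_iter = 800, seed = 13)
  lib <- do.call(rbind, lapply(1:4, function(k) rbind(
    data.frame(id = paste0("ref", k), axis = "ex", wl_nm = m$ex_nm,
               loading = m$ex_loadings[, k]),
    data.frame(id = paste0("ref", k), axis = "em", wl_nm = m$em_nm,
               loading = m$em_loadings[, k]))))
  hit <- match_reference(m, lib)
  expect_equal(hit$congruence, rep(1, 4), tolerance = 1e-9)
  expect_equal(hit$best_match, paste0("ref", 1:4))

  # resampled 1 nm copy of the 2 nm loadings still matches >= 0.999
  lib1 <- do.call(rbind, lapply(1:4, function(k) {
    exf <- seq(min(m$ex_nm), max(m$ex_nm), 1)
    emf <- seq(min(m$em_nm), max(m$em_nm), 1)
    rbind(data.frame(id = paste0("ref", k), axis = "ex", wl_nm = exf,
                     loading = approx(m$ex_nm, m$ex_loadings[, k], exf)$y),
          data.frame(id = paste0("ref", k), axis = "em", wl_nm = emf,
                     loading = approx(m$em_nm, m$em_loadings[, k], emf)$y))
  }))
  expect_true(all(match_reference(m, lib1)$congruence >= 0.999))

  # junk library: narrow peaks far from every fitted component
  junk <- do.call(rbind, lapply(1:2, function(k) rbind(
    data.frame(id = paste0("junk", k), axis = "ex", wl_nm = m$ex_nm,
               loading = exp(-0.5 * ((m$ex_nm - 448) / 3)^2)),
    data.frame(id = paste0("junk", k), axis = "em", wl_nm = m$em_nm,
               loading = exp(-0.5 * ((m$em_nm - 598 + 4 * k) / 3)^2)))))
  expect_true(all(match_reference(m, junk)$congruence < 0.5))
  expect_error(match_reference(m, NULL), class = "fdomlink_argument_error")
})

test_that("model serialization writes loadings, scores and diagnostics", {
  g <- generate_eem_dataset(n_samples = 6, snr = Inf, seed = 15,
                            components = component_specs_default()[c(2, 3)])
  m <- fit_parafac(g$dataset, 2, n_starts = 2, max_iter = 500, seed = 15)
  dir <- withr::local_tempdir()
  write_parafac_model(m, dir)
  sc <- read.csv(file.path(dir, "scores.csv"))
  expect_equal(as.matrix(sc[, -1]), unname(m$scores), ignore_attr = TRUE,
               tolerance = 1e-12)
  dg <- jsonlite::read_json(file.path(dir, "diagnostics.json"))
  expect_equal(dg$n_components, 2)
})
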