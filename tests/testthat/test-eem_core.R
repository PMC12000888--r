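test_that("eem constructor enforces its invariants", {
  expect_s3_class(make_eem(), "eem")
  expect_error(eem("x", c(250, 260), c(300, 310), matrix(0, 3, 2)),
               class = "fdomlink_shape_error")
  expect_error(eem("x", c(260, 250), c(300, 310), matrix(0, 2, 2)),
               class = "fdomlink_format_error")
  expect_error(eem("x", c(250, 260), c(300, 310), matrix(0, 2, 2),
                   corrections = c("trimmed", "trimmed")),
               class = "fdomlink_state_error")
  # units RU iff raman_normalized
  expect_error(eem("x", c(250, 260), c(300, 310), matrix(0, 2, 2),
                   units = "RU"), class = "fdomlink_state_error")
  expect_error(eem("x", c(250, 260), c(300, 310), matrix(0, 2, 2),
                   corrections = "raman_normalized", units = "arbitrary"),
               class = "fdomlink_state_error")
})

test_that("load_eem_csv parses wide matrices, corner cells, and reorders", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Sample,250,260,270",
               "300,1,2,3", "310,4,5,6", "320,7,8,9"), path)
  e <- load_eem_csv(path)
  expect_equal(dim(e$intensity), c(3L, 3L))
  expect_equal(e$ex_nm, c(250, 260, 270))
  expect_equal(e$intensity[2, 3], 6)
  expect_identical(e$corrections, character(0))

  # descending emission rows are reversed together with the intensities
  writeLines(c("Sample,250,260,270",
               "320,7,8,9", "310,4,5,6", "300,1,2,3"), path)
  e2 <- load_eem_csv(path)
  expect_equal(e2$em_nm, c(300, 310, 320))
  expect_equal(e2$intensity, e$intensity)

  writeLines(c("250,260", "300,1,2"), path)
  expect_error(load_eem_csv(path), class = "fdomlink_format_error")
  writeLines(c("Sample,250,260", "300,1,oops"), path)
  expect_error(load_eem_csv(path), "row 2, column 3",
               class = "fdomlink_format_error")
  writeLines(character(0), path)
  expect_error(load_eem_csv(path), class = "fdomlink_format_error")
})

test_that("EEM write/load round-trip is bit-identical", {
  g <- generate_eem_dataset(n_samples = 2, snr = 30, seed = 42,
                            ex_nm = seq(250, 300, 5), em_nm = seq(300, 400, 5))
  e <- g$dataset$eems[[1]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_eem_csv(e, path)
  e2 <- load_eem_csv(path, sample_id = e$sample_id)
  expect_identical(e2$ex_nm, e$ex_nm)
  expect_identical(e2$em_nm, e$em_nm)
  expect_identical(e2$intensity, e$intensity)
})

test_that("subtract_blank is exact elementwise and guards its preconditions", {
  e <- make_eem(function(em, ex) em / 100 + 5)
  blank <- make_eem(function(em, ex) em / 100, id = "blank")
  out <- subtract_blank(e, blank)
  expect_true(all(abs(out$intensity - 5) < 1e-12))
  expect_identical(out$corrections, "blank_subtracted")

  zero <- subtract_blank(blank, blank)
  expect_true(all(zero$intensity == 0))

  # synthetic sample with known additive blank recovers truth
  set.seed(1)
  truth <- make_eem(function(em, ex) abs(sin(em) * cos(ex)))
  b2 <- make_eem(function(em, ex) 0.3 + em / 1000, id = "b")
  obs <- truth; obs$intensity <- truth$intensity + b2$intensity
  expect_lt(max(abs(subtract_blank(obs, b2)$intensity - truth$intensity)),
            1e-12)

  small <- make_eem(ex = c(250, 260), em = c(300, 320, 340))
  expect_error(subtract_blank(e, small), class = "fdomlink_shape_error")
  expect_error(subtract_blank(out, blank), class = "fdomlink_state_error")
})

test_that("inner_filter_correct applies 10^((Aex+Aem)/2)", {
  e <- make_eem(function(em, ex) 2)
  wl <- 200:500
  zero <- absorbance_spectrum("a", wl, rep(0, length(wl)))
  expect_equal(inner_filter_correct(e, zero)$intensity, e$intensity)

  one <- absorbance_spectrum("a", wl, rep(1, length(wl)))
  expect_equal(inner_filter_correct(e, one)$intensity,
               e$intensity * 10, tolerance = 1e-12)

  tenth <- absorbance_spectrum("a", wl, rep(0.1, length(wl)))
  expect_equal(inner_filter_correct(e, tenth)$intensity[1, 1],
               2 * 10^0.1, tolerance = 1e-9)

  # pathlength scaling: 2 cm cell halves the effective absorbance
  two_cm <- absorbance_spectrum("a", wl, rep(0.2, length(wl)),
                                pathlength_cm = 2)
  expect_equal(inner_filter_correct(e, two_cm)$intensity[1, 1], 2 * 10^0.1,
               tolerance = 1e-9)

  gap <- absorbance_spectrum("a", 280:500, rep(0.1, 221))
  expect_error(inner_filter_correct(e, gap), class = "fdomlink_domain_error")
  high <- absorbance_spectrum("a", wl, rep(2, length(wl)))
  expect_warning(inner_filter_correct(e, high), "unreliable")
})

test_that("raman_normalize integrates the blank Raman band", {
  em <- seq(360, 440, 2)
  e <- eem("s", c(340, 350, 360), em, matrix(114, length(em), 3))
  blank1 <- eem("b", c(340, 350, 360), em, matrix(1, length(em), 3))
  out <- raman_normalize(e, blank1)       # band [371, 428], width 57
  expect_equal(out$raman_area, 57)
  expect_true(all(abs(out$eem$intensity - 2) < 1e-12))
  expect_identical(out$eem$units, "RU")

  blank2 <- eem("b", c(340, 350, 360), em, matrix(2, length(em), 3))
  expect_equal(raman_normalize(e, blank2, em_band = c(400, 410))$raman_area,
               20)

  # triangular peak: equals independent trapezoid summation
  tri <- pmax(0, 10 - abs(em - 400))
  blank3 <- eem("b", c(340, 350, 360), em,
                matrix(rep(tri, 3), length(em), 3))
  grid_pts <- c(371, em[em > 371 & em < 428], 428)
  vals <- approx(em, tri, grid_pts)$y
  oracle <- sum(diff(grid_pts) * (vals[-1] + vals[-length(vals)]) / 2)
  expect_equal(raman_normalize(e, blank3)$raman_area, oracle,
               tolerance = 1e-12)

  # scale equivariance: scaling sample and blank by k leaves output unchanged
  ek <- e; ek$intensity <- e$intensity * 3.7
  bk <- blank3; bk$intensity <- blank3$intensity * 3.7
  expect_equal(raman_normalize(ek, bk)$eem$intensity,
               raman_normalize(e, blank3)$eem$intensity, tolerance = 1e-12)

  zero_blank <- eem("b", c(340, 350, 360), em, matrix(0, length(em), 3))
  expect_error(raman_normalize(e, zero_blank),
               class = "fdomlink_normalization_error")
})

test_that("scatter excision refills ridges from the analytic plane", {
  ex <- seq(250, 320, 2); em <- seq(260, 420, 2)
  plane <- function(em, ex) 2 + 0.01 * em + 0.02 * ex
  base <- outer(em, ex, plane)
  spiked <- base
  for (j in seq_along(ex)) {
    hit <- abs(em - ex[j]) <= 8
    spiked[hit, j] <- spiked[hit, j] + 50
  }
  e <- eem("s", ex, em, spiked)
  out <- excise_and_interpolate_scatter(e)
  inside <- outer(em, ex, function(m, x) m >= x - 10)  # not zero-filled
  expect_lt(max(abs((out$intensity - base)[inside])), 1e-9)
  expect_true(all(out$intensity[!inside] == 0))

  # cells outside the declared bands are never altered
  ridge_or_zero <- outer(em, ex, function(m, x) {
    raman <- 1 / (1 / x - 0.00036)
    abs(m - x) <= 10 | abs(m - raman) <= 5 | abs(m - 2 * x) <= 10 | m < x - 10
  })
  expect_identical(out$intensity[!ridge_or_zero], spiked[!ridge_or_zero])

  # widths 0 on a ridge-free EEM (em strictly above ex, no em == 2 ex cell)
  e2 <- eem("s", c(250, 251), c(300, 305, 310),
            matrix(1:6, 3, 2))
  out2 <- excise_and_interpolate_scatter(
    e2, list(rayleigh1 = 0, raman1 = 0, rayleigh2 = 0))
  expect_equal(out2$intensity, e2$intensity)

  const <- eem("s", ex, em, matrix(7, length(em), length(ex)))
  outc <- excise_and_interpolate_scatter(const)
  keep <- outer(em, ex, function(m, x) m >= x - 10)
  expect_true(all(outc$intensity[keep] == 7))
})

test_that("trim_wavelengths keeps the stated ranges", {
  em <- seq(300, 800, 2); ex <- seq(240, 450, 2)
  e <- eem("s", ex, em, matrix(1, length(em), length(ex)))
  out <- trim_wavelengths(e)
  expect_equal(sum(out$em_nm <= 600), length(out$em_nm))
  expect_equal(length(out$em_nm), 151)          # 300..600 step 2
  expect_equal(out$ex_nm[1], 250)               # 240-248 removed
  expect_error(trim_wavelengths(e, em_max = 200),
               class = "fdomlink_trim_error")
  expect_error(trim_wavelengths(out, 600, 250),
               class = "fdomlink_state_error")  # re-application refused
})

test_that("all five corrections refuse re-application", {
  wl <- 200:700
  a <- absorbance_spectrum("a", wl, rep(0.01, length(wl)))
  e <- make_eem(function(em, ex) 1 + em / 100, ex = seq(250, 360, 10),
                em = seq(300, 500, 10))
  blank <- make_eem(function(em, ex) 0.1, ex = seq(250, 360, 10),
                    em = seq(300, 500, 10), id = "b")
  e1 <- subtract_blank(e, blank)
  expect_error(subtract_blank(e1, blank), class = "fdomlink_state_error")
  e2 <- inner_filter_correct(e1, a)
  expect_error(inner_filter_correct(e2, a), class = "fdomlink_state_error")
  e3 <- raman_normalize(e2, blank)$eem
  expect_error(raman_normalize(e3, blank), class = "fdomlink_state_error")
  e4 <- excise_and_interpolate_scatter(e3)
  expect_error(excise_and_interpolate_scatter(e4),
               class = "fdomlink_state_error")
  e5 <- trim_wavelengths(e4, em_max = 480, ex_min = 260)
  expect_error(trim_wavelengths(e5), class = "fdomlink_state_error")
  expect_identical(e5$corrections, c("blank_subtracted", "ife_corrected",
                                     "raman_normalized", "scatter_excised",
                                     "trimmed"))
})

test_that("harmonize_grid interpolates onto the shared grid", {
  e1 <- make_eem(function(em, ex) em + ex)       # ex 250..300 by 10
  ds <- harmonize_grid(list(e1, make_eem(function(em, ex) em - ex, id = "t2")))
  expect_equal(ds$eems[["t1"]]$intensity, e1$intensity)

  # 1 nm sample resampled onto a 2 nm target keeps values at shared knots
  f <- function(em, ex) 3 * em + 2 * ex          # bilinear-exact surface
  fine <- make_eem(f, ex = seq(250, 300, 1), em = seq(300, 400, 1), id = "f")
  coarse <- make_eem(f, ex = seq(250, 300, 2), em = seq(300, 400, 2), id = "c")
  ds2 <- harmonize_grid(list(fine, coarse))
  expect_equal(ds2$ex_nm, coarse$ex_nm)
  expect_lt(max(abs(ds2$eems[["f"]]$intensity - coarse$intensity)), 1e-12)

  far <- make_eem(ex = seq(500, 550, 10), em = seq(600, 700, 20), id = "far")
  expect_error(harmonize_grid(list(e1, far)), class = "fdomlink_domain_error")
})

test_that("metadata loader validates vocabularies", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tmatrix_type\tgroup\tdoc_mg_per_L",
               "s1\twater\tHH\t5.2", "s2\tsediment\tR\t12.0"), path)
  meta <- load_metadata_tsv(path)
  expect_equal(nrow(meta), 2)
  writeLines(c("sample_id\tmatrix_type\tgroup\tdoc_mg_per_L",
               "s1\tlava\tHH\t5.2"), path)
  expect_error(load_metadata_tsv(path), class = "fdomlink_format_error")
  writeLines(c("sample_id\tmatrix_type\tgroup\tdoc_mg_per_L",
               "s1\twater\tHH\t-1"), path)
  expect_error(load_metadata_tsv(path), class = "fdomlink_format_error")
})
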