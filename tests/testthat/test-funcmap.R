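gridInt <- function(grid, vals) mean(vals) * 1  # uniform open grid on (0,1)

test_that("logit-normal densities normalize, center and peak correctly", {
  grid <- densityGrid(20000)
  h <- 1 / 20000
  for (par in list(c(0.5, 0.1), c(0.1, 0.05), c(0.85, 0.15))) {
    d <- logitNormalDensity(grid, par[1], par[2])
    expect_equal(sum(d) * h, 1, tolerance = 1e-4)
  }
  # symmetric about 0.5 when centered there
  d <- logitNormalDensity(grid, 0.5, 0.1)
  expect_equal(d, rev(d), tolerance = 1e-9)
  # mode close to the nominal center (the delta-method latent sd is wide
  # near the boundary, shifting the mode proximally by ~0.02 here)
  d2 <- logitNormalDensity(grid, 0.1, 0.05)
  expect_lt(abs(grid[which.max(d2)] - 0.1), 0.025)
  # boundary continuity
  expect_equal(logitNormalDensity(c(0, 1, -0.5, 2), 0.3, 0.1), rep(0, 4))
  expect_error(logitNormalDensity(0.5, center = 0, sd = 0.1), "center")
  # latent mode: sd used directly on the logit scale
  dl <- logitNormalDensity(grid, 0.5, 0.4, mode = "latent")
  expect_equal(sum(dl) / 20000, 1, tolerance = 1e-4)
})

test_that("default sensilla classes carry the published counts and spatial layout", {
  cl <- defaultSensillaClasses()
  expect_length(cl, 14)
  counts <- c(ab3 = 8, ab1 = 39.825, ab2 = 23, ab4 = 14, ab6 = 15, ab5 = 34,
              ab7 = 11.25, ab8 = 18, ab10 = 18, ab9 = 24,
              at1 = 62.5, at3 = 27, at2 = 15, at4 = 19.5)
  for (nm in names(counts)) expect_equal(cl[[nm]]@count, counts[[nm]])
  expect_equal(cl$ab1@center, 0.1)
  expect_equal(cl$ab9@center, 0.85)
  expect_equal(cl$ab2@center, 0.1 + (0.85 - 0.1) / 8)  # regular interleaving
  expect_equal(cl$ab3@center, 0.05); expect_equal(cl$ab3@sd, 0.05)
  expect_equal(cl$at1@center, 0.65); expect_equal(cl$at3@center, 0.70)
  expect_equal(cl$at2@center, 0.75); expect_equal(cl$at4@center, 0.80)
  expect_true(all(vapply(cl[paste0("at", 1:4)], function(x) x@sd, 1) == 0.15))
  basic <- Filter(function(x) x@family == "basiconic", cl)
  expect_length(basic, 10)
})

test_that("sensilla density integrates to the class count", {
  grid <- densityGrid(5000)
  cl <- defaultSensillaClasses()
  for (nm in c("ab1", "ab3", "at1")) {
    d <- sensillaDensity(cl[[nm]], grid)
    expect_equal(mean(d), cl[[nm]]@count, tolerance = 1e-3)
  }
  # total sensilla on the antenna: sum of the published counts
  total <- Reduce(`+`, lapply(cl, sensillaDensity, grid = grid))
  expect_equal(mean(total), 329.075, tolerance = 1e-3)
})

test_that("response density is linear, additive and zero without responses", {
  grid <- densityGrid(500)
  cl <- defaultSensillaClasses()
  expect_message(responseDensity(cl, grid), "without response data")
  expect_equal(densityValues(responseDensity(cl, grid, quiet = TRUE)),
               numeric(500))
  # one responding class reproduces its own sensilla density
  cl$ab3@responses <- 1
  d1 <- densityValues(responseDensity(cl, grid, quiet = TRUE))
  expect_equal(d1, sensillaDensity(cl$ab3, grid))
  # additivity over class partitions and 1-homogeneity
  cl$ab9@responses <- c(2, 0.5)
  dAll <- densityValues(responseDensity(cl, grid, quiet = TRUE))
  expect_equal(dAll, d1 + 2.5 * sensillaDensity(cl$ab9, grid))
  cl$ab3@responses <- 3; cl$ab9@responses <- c(6, 1.5)
  expect_equal(densityValues(responseDensity(cl, grid, quiet = TRUE)),
               3 * dAll, tolerance = 1e-12)
})

test_that("compartment averages reduce curves correctly", {
  m <- buildModel(speciesGeometry("Dmel"), c(0, 1/3, 2/3, 1))
  grid <- densityGrid(6000)
  # constant curve: all means equal
  cc <- new("ResponseDensityCurve", grid = grid, density = rep(4.2, 6000))
  expect_equal(compartmentAverage(cc, m), rep(4.2, 4))
  # curve supported in window 1 only
  supp <- as.numeric(grid < 1 / 6)
  c1 <- new("ResponseDensityCurve", grid = grid, density = supp)
  expect_equal(compartmentAverage(c1, m)[2:4], rep(0, 3))
  # linear curve: means equal window-midpoint values
  lin <- new("ResponseDensityCurve", grid = grid, density = 2 * grid + 1)
  mids <- compartmentMidpoints(m)
  expect_equal(compartmentAverage(lin, m), 2 * mids + 1, tolerance = 1e-3)
  # too-coarse grid warns
  coarse <- new("ResponseDensityCurve", grid = densityGrid(20),
                density = rep(1, 20))
  w <- testthat::capture_warnings(compartmentAverage(coarse, m))
  expect_true(any(grepl("finer grid", w)))
})

test_that("truncated-Gaussian kernels give similar per-window averages", {
  # robustness of the spatial model: swapping the logit-normal for a
  # renormalized truncated Gaussian changes 4-window averages < 15 %
  m <- buildModel(speciesGeometry("Dmel"), c(0, 1/3, 2/3, 1))
  grid <- densityGrid(4000)
  cl <- defaultSensillaClasses()
  for (cls in cl[c("ab1", "ab3", "ab5", "ab9")]) {
    dLogit <- sensillaDensity(cls, grid)
    g <- dnorm(grid, cls@center, cls@sd)
    dGauss <- cls@count * g / mean(g)
    avL <- compartmentAverage(new("ResponseDensityCurve", grid = grid,
                                  density = dLogit), m)
    avG <- compartmentAverage(new("ResponseDensityCurve", grid = grid,
                                  density = dGauss), m)
    # compare the windows holding the bulk of the class; the logit-normal
    # tails reach farther than Gaussian ones by construction
    big <- avL > 0.2 * max(avL)
    expect_lt(max(abs(avG[big] - avL[big]) / avL[big]), 0.15)
  }
})

test_that("response tables attach per-ORN responses to the right classes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sensillum_class,orn_id,response",
               "ab3,ab3A,0.8", "ab3,ab3B,0.1", "at3,at3A,0.4"), path)
  cl <- readResponseTable(path)
  expect_equal(cl$ab3@responses, c(0.8, 0.1))
  expect_equal(cl$at3@responses, 0.4)
  expect_length(cl$ab1@responses, 0)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("foo,bar\n1,2", bad)
  expect_error(readResponseTable(bad), "sensillum_class")
})
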