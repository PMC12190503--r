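# VAR(1) surrogate generator: determinism, stationarity, attenuation
# bookkeeping and study round trips.

test_that("var_model validates coupling and noise", {
  expect_error(var_model(matrix(1, 2, 3)), "square")
  expect_error(var_model(diag(0.5, 2), noise_sd = 0), "positive")
  m <- var_model(diag(c(0.9, 0.3)))
  expect_equal(m$spectral_radius, 0.9)
})

test_that("generation is deterministic and rejects bad inputs", {
  m <- var_model(diag(0.5, 3))
  x1 <- generate_var_subject(m, 100, seed = 9)
  x2 <- generate_var_subject(m, 100, seed = 9)
  expect_identical(x1, x2)
  x3 <- generate_var_subject(m, 100, seed = 10)
  expect_false(identical(x1, x3))
  bad <- var_model(diag(1.2, 2))
  expect_error(generate_var_subject(bad, 100, seed = 1),
               "spectral radius 1.2")
  expect_error(generate_var_subject(m, 49, seed = 1), "at least 50")
})

test_that("white-noise model reproduces the identity covariance", {
  m <- var_model(matrix(0, 3, 3))
  x <- generate_var_subject(m, 5000, seed = 21)
  expect_lt(max(abs(cov(x) - diag(3))), 0.05)
})

test_that("sample covariance converges to the Lyapunov solution", {
  A <- matrix(c(0.5, 0.2, 0.0,
                0.1, 0.4, 0.2,
                0.0, 0.3, 0.3), 3, 3, byrow = TRUE)
  m <- var_model(A, noise_sd = c(1, 0.8, 1.2))
  S <- stationary_covariance(m)
  # the Lyapunov fixed point satisfies S = A S A' + Q
  expect_equal(S, A %*% S %*% t(A) + diag(c(1, 0.8, 1.2)^2),
               tolerance = 1e-12)
  x <- generate_var_subject(m, 1e5, seed = 22)
  rel <- norm(cov(x) - S, "F") / norm(S, "F")
  expect_lt(rel, 0.02)
})

test_that("attenuation shrinks the affected node's coupling from its stage on", {
  m <- var_model(matrix(0.1, 4, 4) + diag(0.2, 4))
  design <- study_design(c(CN = 3, EMCI = 3, LMCI = 3, AD = 3),
                         affected = data.frame(stage = "EMCI", node = 2L,
                                               factor = 0.3),
                         n_timepoints = 60, seed = 1)
  st <- generate_study(design, m)
  row_strength <- vapply(st$stage_models, function(sm) {
    mean(abs(sm$coupling[2, -2]))
  }, numeric(1))
  expect_equal(row_strength[["CN"]], 0.1)
  expect_equal(unname(row_strength[c("EMCI", "LMCI", "AD")]), rep(0.03, 3))
  for (s in c("EMCI", "LMCI", "AD")) {
    expect_lt(row_strength[[s]], row_strength[["CN"]])
    # columns attenuate too, and other rows keep their couplings
    expect_equal(st$stage_models[[s]]$coupling[3, 2], 0.03)
    expect_equal(st$stage_models[[s]]$coupling[3, 4], 0.1)
  }
  expect_equal(st$ground_truth[[1]]$transition, "CN-EMCI")
  expect_equal(st$ground_truth[[1]]$nodes, 2L)
})

test_that("no attenuation means one shared generative model", {
  m <- var_model(diag(0.4, 3))
  design <- study_design(c(CN = 2, AD = 2), n_timepoints = 60, seed = 3)
  st <- generate_study(design, m)
  expect_identical(st$stage_models$CN$coupling, st$stage_models$AD$coupling)
})

test_that("study bookkeeping: counts, shapes and derived seeds", {
  st <- tiny_study(seed = 5, n_regions = 2, n_timepoints = 70,
                   stages = c(CN = 3, AD = 4))
  expect_length(st$series, 7L)
  for (x in st$series) expect_equal(dim(x), c(70L, 2L))
  expect_equal(as.vector(table(st$manifest$stage)[c("CN", "AD")]), c(3L, 4L))
  # same design seed reproduces the study bit for bit
  st2 <- tiny_study(seed = 5, n_regions = 2, n_timepoints = 70,
                    stages = c(CN = 3, AD = 4))
  expect_identical(st$series, st2$series)
})

test_that("design validation rejects inconsistent attenuation tables", {
  expect_error(study_design(c(CN = 0, AD = 2)), "positive")
  expect_error(study_design(c(3, 4)), "named")
  expect_error(study_design(c(CN = 2, AD = 2),
                            affected = data.frame(stage = "CN", node = 1,
                                                  factor = 0.5)),
               "first")
  expect_error(study_design(c(CN = 2, AD = 2),
                            affected = data.frame(stage = "AD", node = 1,
                                                  factor = 1.5)),
               "\\(0, 1\\]")
  d <- study_design(c(CN = 2, AD = 2),
                    affected = data.frame(stage = "AD", node = 99,
                                          factor = 0.5))
  expect_error(generate_study(d, var_model(diag(0.4, 3))), "outside")
})

test_that("write_study / read_study round-trips every numeric exactly", {
  st <- tiny_study(seed = 6)
  dir <- tempfile()
  write_study(st, dir)
  back <- read_study(dir)
  for (id in names(st$series)) {
    expect_equal(back$series[[id]], st$series[[id]], tolerance = 0)
  }
  expect_equal(back$manifest, st$manifest)
  expect_equal(back$metadata$region, st$metadata$region)
  expect_equal(back$metadata$x_mm, st$metadata$x_mm, tolerance = 0)
  expect_equal(back$ground_truth[[1]]$transition, "CN-AD")
})

test_that("malformed studies are rejected with named diagnostics", {
  st <- tiny_study(seed = 7)
  dir <- tempfile()
  write_study(st, dir)
  file.remove(file.path(dir, "series", "sub-002.tsv"))
  expect_error(read_study(dir), "sub-002")

  dir2 <- tempfile()
  write_study(st, dir2)
  md <- read.delim(file.path(dir2, "metadata.tsv"))
  md$region[2] <- md$region[1]
  write.table(md, file.path(dir2, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_study(dir2), "duplicated region")

  dir3 <- tempfile()
  write_study(st, dir3)
  f <- file.path(dir3, "series", "sub-001.tsv")
  lines <- readLines(f)
  lines[3] <- sub("^[^\t]+", "NaN", lines[3])
  writeLines(lines, f)
  expect_error(read_study(dir3), "non-finite value at line 3")
})

test_that("node metadata is valid and deterministic", {
  md <- node_metadata(20, seed = 3)
  expect_false(anyDuplicated(md$region) > 0)
  expect_true(all(md$network %in% c("VIS", "SMN", "DAN", "VAN",
                                    "LN", "FN", "DMN", "OTH")))
  expect_identical(md, node_metadata(20, seed = 3))
})
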