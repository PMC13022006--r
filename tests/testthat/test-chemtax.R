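test_that("ratio matrices carry the expected structure", {
  for (m in list(ratio_matrix_initial(), ratio_matrix_final())) {
    expect_equal(dim(m), c(8, 15))
    expect_true(all(m >= 0))
    expect_equal(unname(m[, "Chl a"]), rep(1, 8))
    # peridinin is diagnostic for dinoflagellates only
    expect_equal(sum(m[, "Perid"] > 0), 1)
    expect_true(m["Dinoflagellates1", "Perid"] > 0)
  }
  # the packaged text fixtures are the in-code matrices verbatim
  for (nm in c("initial", "final")) {
    p <- system.file("extdata", sprintf("ratio_%s.tsv", nm),
                     package = "sestonmix")
    m <- read_ratio_matrix(p)
    ref <- if (nm == "initial") ratio_matrix_initial() else
      ratio_matrix_final()
    expect_equal(m, ref)
  }
})

test_that("fit_composition is exact on noise-free mixtures", {
  Ff <- ratio_matrix_final()
  # single class, scaled
  s <- matrix(0.5 * Ff["Diatoms1", ], 1,
              dimnames = list("d", colnames(Ff)))
  fc <- fit_composition(s, Ff)
  expect_equal(fc$contribution[1, "Diatoms1"], 0.5, tolerance = 1e-9)
  expect_equal(unname(fc$percent[1, "Diatoms1"]), 100, tolerance = 1e-9)
  # two-class 30/70 mixture
  s2 <- matrix(0.3 * Ff["Haptophytes6", ] + 0.7 * Ff["Cyanobacteria2", ],
               1, dimnames = list("m", colnames(Ff)))
  fc2 <- fit_composition(s2, Ff)
  expect_equal(unname(fc2$percent[1, c("Haptophytes6", "Cyanobacteria2")]),
               c(30, 70), tolerance = 1e-6)
  expect_lt(fc2$objective, 1e-10)
  # random mixtures round-trip through the solver
  g <- gen_pigment_samples(10, cv = 0, seed = 21)
  fc3 <- fit_composition(g$pigments, Ff)
  expect_equal(unname(fc3$percent / 100), unname(g$fractions),
               tolerance = 1e-6)
  # percents sum to 100 where chl a is present
  expect_equal(unname(rowSums(fc3$percent)), rep(100, 10),
               tolerance = 1e-6)
})

test_that("fit_composition agrees with independent NNLS and grid oracles", {
  skip_if_not_installed("pracma")
  Ff <- ratio_matrix_final()
  g <- gen_pigment_samples(5, cv = 0.05, seed = 31)
  S <- g$pigments
  fc <- fit_composition(S, Ff)
  w <- 1 / sqrt(colMeans(S^2))
  w[!is.finite(w)] <- 0
  A <- t(Ff * rep(w, each = nrow(Ff)))
  for (i in seq_len(nrow(S))) {
    x_ref <- pracma::lsqnonneg(A, S[i, ] * w)$x
    expect_equal(unname(fc$contribution[i, ]), x_ref, tolerance = 1e-6)
  }
  # 2-class coarse grid-search oracle
  F2 <- Ff[c("Diatoms1", "Cryptophytes"), ]
  s <- matrix(0.4 * F2[1, ] + 0.25 * F2[2, ], 1,
              dimnames = list("x", colnames(F2)))
  fc2 <- fit_composition(s, F2, weighting = "none")
  grid <- seq(0, 1, by = 0.005)
  obj <- outer(grid, grid, Vectorize(function(a, b)
    sum((s[1, ] - a * F2[1, ] - b * F2[2, ])^2)))
  best <- arrayInd(which.min(obj), dim(obj))
  expect_equal(unname(fc2$contribution[1, ]),
               c(grid[best[1]], grid[best[2]]), tolerance = 0.005)
})

test_that("a pigment foreign to all classes adds residual, not bias", {
  Ff <- ratio_matrix_final()
  # zero out a pigment across classes, then put signal there in the sample
  F0 <- Ff
  F0[, "Lut"] <- 0
  s <- matrix(0.8 * F0["Prasinophytes3", ], 1,
              dimnames = list("x", colnames(F0)))
  s[1, "Lut"] <- 0.3
  fc_with <- fit_composition(s, F0)
  fc_drop <- fit_composition(s[, colnames(F0) != "Lut", drop = FALSE],
                             F0[, colnames(F0) != "Lut"])
  expect_gt(fc_with$objective, 0)
  expect_equal(fc_with$contribution, fc_drop$contribution,
               tolerance = 1e-9)
})

test_that("all-zero pigment rows yield zero composition with a warning", {
  Ff <- ratio_matrix_final()
  S <- rbind(0.5 * Ff["Diatoms1", ], 0)
  rownames(S) <- c("a", "b")
  expect_warning(fc <- fit_composition(S, Ff), "all-zero")
  expect_equal(unname(fc$contribution["b", ]), rep(0, 8))
  expect_equal(unname(fc$percent["b", ]), rep(0, 8))
})

test_that("ratio-matrix perturbation is bounded, structured and seeded", {
  F0 <- ratio_matrix_initial()
  expect_equal(perturb_ratio_matrix(F0, 0, seed = 1), F0)
  expect_equal(perturb_ratio_matrix(F0, 0.35, seed = 9),
               perturb_ratio_matrix(F0, 0.35, seed = 9))
  F1 <- perturb_ratio_matrix(F0, 0.35, seed = 10)
  expect_equal(F1 == 0, F0 == 0)           # structural zeros preserved
  expect_equal(F1[, "Chl a"], F0[, "Chl a"])
  nz <- F0 != 0 & col(F0) != which(colnames(F0) == "Chl a")
  expect_true(all(abs(F1[nz] / F0[nz] - 1) <= 0.35))
  expect_error(perturb_ratio_matrix(F0, 1), "magnitude")
  # unbiased: the mean over many draws of one entry is the original value
  draws <- vapply(1:10000, function(s)
    perturb_ratio_matrix(F0, 0.35, seed = s)["Diatoms1", "Fuco"],
    numeric(1))
  expect_equal(mean(draws), F0["Diatoms1", "Fuco"], tolerance = 0.01)
})

test_that("ratio-matrix optimization descends within bounds", {
  Ff <- ratio_matrix_final()
  g <- gen_pigment_samples(6, cv = 0, seed = 41)
  # noise-free data generated from F_init: nothing to improve
  opt0 <- optimize_ratio_matrix(g$pigments, Ff, max_iter = 3)
  expect_lt(opt0$objective, 1e-8)
  expect_equal(opt0$F, Ff)
  # max_iter = 0 is a no-op
  optn <- optimize_ratio_matrix(g$pigments, Ff, max_iter = 0)
  expect_equal(optn$F, Ff)
  expect_length(optn$trace, 1)
  # planted misfit: one Fuco ratio scaled x1.2 in the generator
  Fgen <- Ff
  Fgen["Diatoms1", "Fuco"] <- 1.2 * Ff["Diatoms1", "Fuco"]
  g2 <- gen_pigment_samples(8, ratio_matrix = Fgen, cv = 0, seed = 42)
  opt <- optimize_ratio_matrix(g2$pigments, Ff, max_iter = 8)
  expect_true(all(diff(opt$trace) <= 1e-12))  # non-increasing
  expect_lt(opt$objective, opt$trace[1])
  expect_gt(opt$F["Diatoms1", "Fuco"], Ff["Diatoms1", "Fuco"])
  # entries stay inside the multiplicative box
  nz <- Ff != 0 & col(Ff) != which(colnames(Ff) == "Chl a")
  expect_true(all(opt$F[nz] / Ff[nz] >= 0.5 - 1e-9 &
                    opt$F[nz] / Ff[nz] <= 1.5 + 1e-9))
  expect_equal(opt$F == 0, Ff == 0)
})

test_that("chemtax_run degenerates to fit_composition and is seed-stable", {
  Ff <- ratio_matrix_final()
  g <- gen_pigment_samples(5, cv = 0.02, seed = 51)
  run <- chemtax_run(g$pigments, Ff, n_random = 1, n_runs = 1, n_best = 1,
                     magnitude = 0, max_iter = 0, seed = 3)
  ref <- fit_composition(g$pigments, Ff)
  expect_equal(run$composition$percent, ref$percent)
  expect_equal(run$F, Ff)
  # magnitude 0 makes the whole run invariant under the seed
  run2 <- chemtax_run(g$pigments, Ff, n_random = 2, n_runs = 1, n_best = 1,
                      magnitude = 0, max_iter = 0, seed = 99)
  expect_equal(run2$composition$percent, run$composition$percent)
  expect_error(chemtax_run(g$pigments, Ff, n_random = 2, n_best = 3),
               "n_best")
})

test_that("the randomized multi-run search improves across runs", {
  Ff <- ratio_matrix_final()
  g <- gen_pigment_samples(6, cv = 0.01, seed = 61)
  run <- chemtax_run(g$pigments, Ff, n_random = 6, n_runs = 3, n_best = 2,
                     magnitude = 0.2, max_iter = 3, seed = 8)
  best <- run$diagnostics$best_objective_per_run
  expect_length(best, 3)
  expect_true(all(diff(best) <= 1e-12))  # best objective never worsens
  # recovered percents stay close to the generating fractions
  mae <- mean(abs(run$composition$percent / 100 - g$fractions)) * 100
  expect_lt(mae, 5)
})
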