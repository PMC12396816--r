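test_that("closed-form parameter counts match the reference model shapes", {
  expect_identical(countParams(thriftyConfig(11, 7, 19, 0.3, "joined")), 2057L)
  expect_identical(countParams(thriftyConfig(9, 7, 16, 0.2, "independent")), 4539L)
  expect_identical(countParams(thriftyConfig(11, 7, 19, 0.3, "independent")), 5931L)
  # minimal joined config, evaluated by hand: 67 + 2 + 10 = 79
  expect_identical(countParams(thriftyConfig(1, 1, 1, 0, "joined")), 79L)
})

test_that("formula equals exhaustive weight enumeration across a config grid", {
  for (K in c(1L, 3L, 9L, 11L)) {
    for (E in c(1L, 4L, 7L)) {
      for (F in c(1L, 8L, 19L)) {
        for (w in c("joined", "hybrid", "independent")) {
          cfg <- thriftyConfig(K, E, F, 0.1, w)
          m <- buildThriftyModel(cfg, seed = 1)
          expect_identical(nParams(m), countParams(cfg),
                           label = sprintf("K=%d E=%d F=%d %s", K, E, F, w))
        }
      }
    }
  }
})

test_that("effective context is kernel + 2", {
  expect_identical(receptiveField(thriftyConfig(kernel = 9)), 11L)
  expect_identical(receptiveField(thriftyConfig(kernel = 11)), 13L)
  expect_identical(receptiveField(thriftyConfig(kernel = 3)), 5L)
  expect_identical(receptiveField(9), 11L)
  expect_error(thriftyConfig(kernel = 4), "odd")
  expect_error(receptiveField(4), "odd")
})

test_that("invalid configurations are rejected", {
  expect_error(thriftyConfig(embed = 0), "embed")
  expect_error(thriftyConfig(filters = 0), "filters")
  expect_error(thriftyConfig(dropout = 1), "dropout")
  expect_error(thriftyConfig(wiring = "parallel"), "wiring")
})

test_that("forward pass has the contract shapes and CSP structure", {
  for (w in c("joined", "hybrid", "independent")) {
    m <- buildThriftyModel(thriftyConfig(11, 7, 19, 0.3, w), seed = 2)
    s <- randomParent(100, seed = 3)
    pred <- predictRates(m, s)
    expect_length(siteRates(pred), 100L)
    expect_true(all(siteRates(pred) > 0))
    csp <- cspMatrix(pred)
    expect_identical(dim(csp), c(100L, 4L))
    expect_equal(rowSums(csp), rep(1, 100))
    ch <- strsplit(s, "")[[1]]
    expect_true(all(csp[cbind(1:100, match(ch, NUC))] == 0))
  }
})

test_that("ambiguous parent sites are flagged with NA CSP rows", {
  m <- buildThriftyModel(thriftyConfig(3, 4, 8, 0, "joined"), seed = 2)
  pred <- predictRates(m, "ACGNACGT")
  expect_identical(which(pred@flagged), 4L)
  expect_true(all(is.na(cspMatrix(pred)[4, ])))
  expect_true(all(!is.na(cspMatrix(pred)[-4, ])))
})

test_that("same seed and config give bit-identical weights", {
  cfg <- thriftyConfig(9, 5, 12, 0.2, "hybrid")
  m1 <- buildThriftyModel(cfg, seed = 99)
  m2 <- buildThriftyModel(cfg, seed = 99)
  expect_identical(m1@weights, m2@weights)
  m3 <- buildThriftyModel(cfg, seed = 100)
  expect_false(identical(m1@weights, m3@weights))
})

test_that("zero head weights give constant rate exp(bias)", {
  m <- buildThriftyModel(thriftyConfig(5, 3, 6, 0, "joined"), seed = 4)
  m@weights$rateW[] <- 0
  m@weights$rateB <- 0.7
  pred <- predictRates(m, randomParent(50, seed = 5))
  expect_equal(siteRates(pred), rep(exp(0.7), 50))
})

test_that("predictions are invariant to perturbations outside the K+2 window", {
  for (K in c(3L, 9L)) {
    m <- buildThriftyModel(thriftyConfig(K, 4, 8, 0.2, "independent"), seed = 6)
    half <- (K + 1L) / 2L
    set.seed(8)
    ch <- sample(NUC, 41, replace = TRUE)
    base <- predictRates(m, paste0(ch, collapse = ""))
    focal <- 21L
    for (pos in seq_along(ch)) {
      ch2 <- ch
      ch2[pos] <- setdiff(NUC, ch[pos])[1]
      pert <- predictRates(m, paste0(ch2, collapse = ""))
      if (abs(pos - focal) > half) {
        expect_equal(pert@rates[focal], base@rates[focal])
        if (pos != focal) expect_equal(pert@csp[focal, ], base@csp[focal, ])
      }
    }
    expect_identical(empiricalContextWidth(m, length = 41, nSeq = 3, seed = 9),
                     K + 2L)
  }
})

test_that("a K=1 model depends only on the centered 3-mer (all 64 3-mers)", {
  m <- buildThriftyModel(thriftyConfig(1, 5, 9, 0, "joined"), seed = 10)
  # two long random sequences; sites sharing a 3-mer must agree exactly
  s1 <- randomParent(400, seed = 11)
  s2 <- randomParent(400, seed = 12)
  p1 <- predictRates(m, s1); p2 <- predictRates(m, s2)
  t1 <- tokenize3mers(s1); t2 <- tokenize3mers(s2)
  seen <- intersect(t1[t1 < 64], t2[t2 < 64])
  expect_length(seen, 64L) # all 3-mers occur at length 400
  for (tok in seen) {
    i <- which(t1 == tok)[1]; j <- which(t2 == tok)[1]
    expect_equal(p1@rates[i], p2@rates[j])
    expect_equal(p1@csp[i, ], p2@csp[j, ])
  }
})

test_that("interior predictions are translation covariant on periodic sequences", {
  m <- buildThriftyModel(thriftyConfig(3, 4, 8, 0, "joined"), seed = 13)
  s <- strrep("ACGGT", 12) # period 5, length 60
  pred <- predictRates(m, s)
  inner <- 11:49 # away from boundaries
  expect_equal(pred@rates[inner], pred@rates[inner + 5])
})

test_that("5-mer model ignores bases beyond distance 2", {
  fv <- buildFivemerModel(seed = 14, sdLog = 0.5)
  set.seed(15)
  ch <- sample(NUC, 21, replace = TRUE)
  base <- predictRates(fv, paste0(ch, collapse = ""))
  focal <- 11L
  for (pos in seq_along(ch)) {
    ch2 <- ch
    ch2[pos] <- setdiff(NUC, ch[pos])[1]
    pert <- predictRates(fv, paste0(ch2, collapse = ""))
    if (abs(pos - focal) > 2) {
      expect_equal(pert@rates[focal], base@rates[focal])
    }
  }
  expect_identical(empiricalContextWidth(fv, length = 21, nSeq = 2, seed = 16), 5L)
})

test_that("increasing the rate-head bias strictly increases every rate", {
  m <- buildThriftyModel(thriftyConfig(3, 4, 8, 0.3, "joined"), seed = 17)
  s <- randomParent(60, seed = 18)
  r1 <- siteRates(predictRates(m, s))
  m@weights$rateB <- m@weights$rateB + 0.5
  r2 <- siteRates(predictRates(m, s))
  expect_true(all(r2 > r1))
})

test_that("model serialization round-trips to identical predictions", {
  s <- randomParent(80, seed = 19)
  models <- list(
    buildThriftyModel(thriftyConfig(9, 7, 16, 0.2, "independent"), seed = 20),
    buildFivemerModel(seed = 21, sdLog = 0.3),
    buildSitewiseFivemerModel(c(0L, 79L), seed = 22)
  )
  for (m in models) {
    path <- withr::local_tempfile(fileext = ".json")
    saveModel(m, path)
    back <- loadModel(path)
    expect_identical(siteRates(predictRates(back, s)), siteRates(predictRates(m, s)))
    expect_identical(cspMatrix(predictRates(back, s)), cspMatrix(predictRates(m, s)))
  }
  expect_error(loadModel("/nonexistent/model.json"), "not found")
})

test_that("schema-version mismatches are rejected", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema":"thriftySHM-model/99","type":"thrifty"}', path)
  expect_error(loadModel(path), "schema")
})

test_that("sitewise 5-mer model multiplies per-site factors over its range", {
  m <- buildSitewiseFivemerModel(c(2L, 5L), seed = 23)
  m@logSiteFactor <- c(1, 0, 0, 0.5)
  s <- "ACGTACGTAC"
  r <- siteRates(predictRates(m, s))
  base <- siteRates(predictRates(m@fivemer, s))
  expect_equal(r[3], base[3] * exp(1)) # 0-based site 2
  expect_equal(r[6], base[6] * exp(0.5)) # 0-based site 5
  expect_equal(r[c(1, 2, 7:10)], base[c(1, 2, 7:10)])
})
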