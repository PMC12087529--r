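mkEffects <- function(n, nScheme, mu, tauSp, tauSc, seMin = 0.05,
                      seMax = 0.5, seed = 1) {
  set.seed(seed)
  scheme <- sprintf("s%02d", sample(nScheme, n, replace = TRUE))
  a <- stats::rnorm(nScheme, 0, tauSc)
  names(a) <- sprintf("s%02d", seq_len(nScheme))
  se <- stats::runif(n, seMin, seMax)
  data.frame(species_id = sprintf("sp%04d", seq_len(n)),
             scheme_id = scheme,
             estimate = mu + a[scheme] + stats::rnorm(n, 0, tauSp) +
               stats::rnorm(n, 0, se),
             se = se, stringsAsFactors = FALSE)
}

test_that("the degenerate limit collapses onto the common value", {
  eff <- data.frame(species_id = sprintf("sp%d", 1:30),
                    scheme_id = rep(c("a", "b", "c"), 10),
                    estimate = 0.42, se = 1e-4)
  m <- fitMeta(eff, nIter = 800, nChains = 2, warmup = 200, seed = 1)
  s <- effectSummary(m)
  expect_lt(abs(s$mean[s$parameter == "mu"] - 0.42), 0.01)
  expect_lt(s$`q97.5`[s$parameter == "tau_species"], 0.05)
  expect_lt(s$`q97.5`[s$parameter == "tau_scheme"], 0.25)
})

test_that("a single scheme matches the DerSimonian-Laird oracle", {
  skip_if_not_installed("metafor")
  eff <- mkEffects(60, 1, mu = 0.2, tauSp = 0.25, tauSc = 0, seed = 3)
  expect_warning(m <- fitMeta(eff, nIter = 1500, nChains = 2,
                              warmup = 300, seed = 4), "single")
  dl <- metafor::rma(yi = eff$estimate, sei = eff$se, method = "DL")
  s <- effectSummary(m)
  muHat <- s$mean[s$parameter == "mu"]
  expect_lt(abs(muHat - as.numeric(dl$beta)),
            2.5 * sqrt(s$sd[s$parameter == "mu"]^2 + dl$se^2))
  expect_lt(abs(s$mean[s$parameter == "tau_species"] - sqrt(dl$tau2)),
            0.1)
})

test_that("shrinkage vanishes as the measurement error goes to zero", {
  eff <- mkEffects(40, 4, mu = 0, tauSp = 0.4, tauSc = 0.05,
                   seMin = 1e-4, seMax = 2e-4, seed = 5)
  m <- fitMeta(eff, nIter = 800, nChains = 2, warmup = 200, seed = 6)
  expect_lt(max(abs(m@speciesShrinkage$theta_mean - eff$estimate)),
            0.01)
})

test_that("the pooled mean is invariant to species order", {
  eff <- mkEffects(120, 5, mu = 0.15, tauSp = 0.3, tauSc = 0.05,
                   seed = 7)
  m1 <- fitMeta(eff, nIter = 1500, nChains = 2, warmup = 300, seed = 8)
  perm <- eff[rev(seq_len(nrow(eff))), ]
  m2 <- fitMeta(perm, nIter = 1500, nChains = 2, warmup = 300,
                seed = 8)
  s1 <- effectSummary(m1); s2 <- effectSummary(m2)
  mcSd <- s1$sd[s1$parameter == "mu"]
  expect_lt(abs(s1$mean[s1$parameter == "mu"] -
                  s2$mean[s2$parameter == "mu"]), 0.5 * mcSd)
})

test_that("a zero between-scheme SD is recovered near the boundary", {
  eff <- mkEffects(300, 10, mu = 0.1, tauSp = 0.3, tauSc = 0, seed = 9)
  m <- fitMeta(eff, nIter = 1500, nChains = 2, warmup = 300, seed = 10)
  expect_lt(stats::quantile(metaDraws(m)$tau_scheme, 0.95), 0.15)
})

test_that("invalid inputs are rejected", {
  eff <- mkEffects(20, 2, 0, 0.1, 0, seed = 11)
  eff$se[3] <- 0
  expect_error(fitMeta(eff), "positive")
  eff2 <- mkEffects(20, 2, 0, 0.1, 0, seed = 11)
  eff2$species_id[2] <- eff2$species_id[1]
  expect_error(fitMeta(eff2), "one row per species")
})

test_that("direction tabulation counts credible-interval signs", {
  mkRes <- function(id, lo, hi) {
    s <- data.frame(effect = "connectivity", mean = (lo + hi) / 2,
                    sd = 1, `q2.5` = lo, `q97.5` = hi,
                    check.names = FALSE)
    methods::new("SpeciesModelResult", speciesId = id, schemeId = "s",
                 variant = "main", backend = "laplace",
                 converged = TRUE, summary = s, nVisits = 10L)
  }
  res <- list(mkRes("a", 0.1, 0.3), mkRes("b", -0.3, -0.1),
              mkRes("c", -0.1, 0.2))
  tab <- tabulateDirections(res, "connectivity")
  expect_equal(tab$count[tab$direction == "positive"], 1L)
  expect_equal(tab$count[tab$direction == "negative"], 1L)
  expect_equal(tab$count[tab$direction == "neither"], 1L)
  expect_equal(sum(tab$percent), 100)
  expect_error(tabulateDirections(list()), "no converged")
})

test_that("a positive pooled mean yields more positive than negative species", {
  set.seed(12)
  eff <- mkEffects(400, 8, mu = 0.148, tauSp = 0.33, tauSc = 0.03,
                   seed = 13)
  res <- lapply(seq_len(nrow(eff)), function(i) {
    s <- data.frame(effect = "connectivity", mean = eff$estimate[i],
                    sd = eff$se[i],
                    `q2.5` = eff$estimate[i] - 1.96 * eff$se[i],
                    `q97.5` = eff$estimate[i] + 1.96 * eff$se[i],
                    check.names = FALSE)
    methods::new("SpeciesModelResult", speciesId = eff$species_id[i],
                 schemeId = eff$scheme_id[i], variant = "main",
                 backend = "laplace", converged = TRUE, summary = s,
                 nVisits = 10L)
  })
  tab <- tabulateDirections(res, "connectivity")
  expect_gt(tab$count[tab$direction == "positive"],
            tab$count[tab$direction == "negative"])
})
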