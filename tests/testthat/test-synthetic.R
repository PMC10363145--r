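# Synthetic-data generator: determinism, planted structure, marginals.

groups4 <- c("Control", "ACA", "17aE2", "Rapa")
sig <- function(x) stats::setNames(rep(x, 4), groups4)
shared <- stats::setNames(rep("O1", 4), groups4)

test_that("the generator is reproducible from the seed and leaves the RNG alone", {
  a <- simulate_intervention_study(seed = 3, n_null = 2)
  b <- simulate_intervention_study(seed = 3, n_null = 2)
  expect_identical(unclass(a$abundance), unclass(b$abundance))
  expect_identical(a$truth$modules$TAS01$orderings, b$truth$modules$TAS01$orderings)
  expect_identical(a$flux$flux, b$flux$flux)
  c_ <- simulate_intervention_study(seed = 4, n_null = 2)
  expect_false(identical(unclass(a$abundance), unclass(c_$abundance)))
  # caller's RNG state is restored
  set.seed(99); before <- .Random.seed
  invisible(simulate_intervention_study(seed = 3, n_null = 2))
  expect_identical(.Random.seed, before)
})

test_that("the noiseless limit gives RCI exactly 1", {
  specs <- lapply(1:3, function(k) {
    module_spec(sprintf("M%d", k), 6, delta = 1, sigma = sig(1e-9),
                consensus = shared)
  })
  s <- generate_abundance(groups4, 6, specs, seed = 11)
  d <- dirac_rms(s$abundance, s$metadata, s$modules)
  expect_true(all(d$rci$rci == 1))
})

test_that("pure-noise modules match the analytic own-consensus null", {
  n_mod <- 400
  specs <- lapply(seq_len(n_mod), function(k) {
    module_spec(sprintf("M%03d", k), 6, delta = 0, sigma = sig(1),
                consensus = shared)
  })
  s <- generate_abundance(groups4, 12, specs, seed = 12)
  d <- dirac_rms(s$abundance, s$metadata, s$modules)
  expected <- oracle_null_rci(12)
  se <- sd(d$rci$rci) / sqrt(nrow(d$rci))
  expect_lt(abs(mean(d$rci$rci) - expected), 3 * se)
})

test_that("adjacent-pair inversion rate follows the Gaussian closed form", {
  # delta/sigma = 2 -> inversion probability pnorm(-sqrt(2)) ~ 0.0786
  n_mod <- 60
  specs <- lapply(seq_len(n_mod), function(k) {
    module_spec(sprintf("M%03d", k), 8, delta = 1, sigma = sig(0.5),
                consensus = shared)
  })
  s <- generate_abundance(groups4, 12, specs, seed = 13)
  v <- unclass(s$abundance)
  mism <- integer(0)
  for (mid in names(s$truth$modules)) {
    ord <- s$truth$modules[[mid]]$orderings$O1
    for (a in seq_len(length(ord) - 1L)) {
      # ord[a] has the higher planted mean than ord[a + 1]
      mism <- c(mism, as.integer(v[ord[a], ] <= v[ord[a + 1L], ]))
    }
  }
  p_hat <- mean(mism)
  p_true <- pnorm(-sqrt(2))
  expect_lt(abs(p_hat - p_true),
            3 * sqrt(p_true * (1 - p_true) / length(mism)))
})

test_that("planted covariate effects are removed by the regression stage", {
  specs <- lapply(1:4, function(k) {
    module_spec(sprintf("M%d", k), 6, delta = 1, sigma = sig(1),
                consensus = shared)
  })
  s <- generate_abundance(groups4, 12, specs, n_background = 40,
                          beta_sd = 1.0, seed = 14)
  adj <- regress_out_covariates(s$abundance, s$metadata)
  # per-analyte F-tests of residuals ~ sex + age must be null-distributed
  design <- data.frame(sex = factor(s$metadata$sex),
                       age = factor(s$metadata$age_months))
  pvals <- apply(unclass(adj), 1L, function(x) {
    if (sd(x) == 0) return(NA_real_)
    fit <- lm(x ~ sex + age, data = design)
    f <- summary(fit)$fstatistic
    pf(f[1L], f[2L], f[3L], lower.tail = FALSE)
  })
  pvals <- pvals[!is.na(pvals)]
  # residual association is numerically nil: every p ~ 1
  expect_gt(min(pvals), 0.99)
  # whereas the raw table carries strong covariate signal
  praw <- apply(unclass(s$abundance), 1L, function(x) {
    fit <- lm(x ~ sex + age, data = design)
    f <- summary(fit)$fstatistic
    pf(f[1L], f[2L], f[3L], lower.tail = FALSE)
  })
  expect_lt(median(praw), 0.5)
})

test_that("distinct orderings honour the pairwise Kendall floor", {
  s <- simulate_intervention_study(seed = 15, n_null = 1)
  for (mid in s$truth$classes$tight_all_distinct) {
    ords <- s$truth$modules[[mid]]$orderings
    expect_identical(length(ords), 4L)  # O1 + one per intervention
    npairs <- choose(length(ords[[1]]), 2)
    for (i in seq_along(ords)) {
      for (j in seq_len(i - 1L)) {
        d <- diracr:::kendall_distance(ords[[i]], ords[[j]])
        expect_gte(d, 0.55 * npairs)
      }
    }
  }
})

test_that("module specs below the coverage minimum are rejected", {
  expect_error(module_spec("M", 3, sigma = sig(1), consensus = shared),
               "< 4")
})

test_that("a study serializes to standard formats and re-reads identically", {
  s <- simulate_intervention_study(seed = 16, n_null = 2,
                                   n_background = 20)
  dir <- withr::local_tempdir()
  paths <- write_study(s, dir)
  ab <- read_abundance(paths[["abundance"]])
  expect_equal(unclass(ab), unclass(s$abundance), tolerance = 1e-12)
  expect_identical(as.data.frame(read_metadata(paths[["metadata"]])),
                   as.data.frame(s$metadata))
  ms <- read_gmt(paths[["modules"]])
  expect_identical(lapply(ms$members, sort), lapply(s$modules$members, sort))
  fl <- read_flux(paths[["flux"]], subsystem_path = paths[["subsystems"]])
  expect_equal(fl$flux, s$flux$flux, tolerance = 1e-12)
  expect_identical(fl$subsystem, s$flux$subsystem)
})

test_that("flux decoys are excluded from the assessed universe, shifts are found", {
  s <- simulate_intervention_study(seed = 17, n_null = 1)
  kept <- filter_functional_reactions(s$flux)
  expect_identical(intersect(rownames(kept$flux), s$flux_truth$decoy_ids),
                   character(0))
  expect_identical(nrow(kept$flux),
                   nrow(s$flux$flux) - length(s$flux_truth$decoy_ids))
  screen <- screen_changed_reactions(kept, s$flux_metadata, s$control,
                                     s$interventions)
  planted <- names(s$flux_truth$shifted)
  aca <- screen[screen$intervention == "ACA", ]
  expect_true(all(aca$changed[aca$reaction_id %in% intersect(planted,
    names(Filter(function(x) "ACA" %in% x$groups, s$flux_truth$shifted)))]))
  # the planted subsystem attains the smallest adjusted p
  enr <- subsystem_enrichment(screen, "ACA")
  expect_identical(enr$subsystem[which.min(enr$p_adj)], "Subsystem 01")
})

test_that("the null study variant plants nothing", {
  s <- simulate_intervention_study(seed = 18, null = TRUE)
  expect_identical(s$truth$classes$tight_all_shared, character(0))
  expect_identical(length(s$flux_truth$shifted), 0L)
  sig_all <- unique(unlist(lapply(s$truth$modules, function(m) m$sigma)))
  expect_identical(length(sig_all), 1L)
})
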