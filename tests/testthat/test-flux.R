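# Flux screening and subsystem enrichment.

flux_fixture <- function(n_rx = 6, groups = c("Control", "Tx"), n = 4,
                         seed = 1) {
  set.seed(seed)
  meta <- sample_metadata(data.frame(
    sample_id = paste0("s", seq_len(n * length(groups))),
    group = rep(groups, each = n),
    sex = "F", age_months = "6"))
  flux <- matrix(rnorm(n_rx * nrow(meta)), n_rx, nrow(meta),
                 dimnames = list(paste0("R", seq_len(n_rx)), meta$sample_id))
  list(meta = meta, flux = flux)
}

test_that("representative flux is the FVA midpoint with ordering checks", {
  lo <- matrix(c(-2, 1), 1, 2, dimnames = list("R1", c("s1", "s2")))
  hi <- matrix(c(4, 1), 1, 2, dimnames = list("R1", c("s1", "s2")))
  expect_equal(representative_flux(lo, hi),
               matrix(c(1, 1), 1, 2, dimnames = dimnames(lo)))
  bad <- hi; bad[1, 2] <- 0.5
  expect_error(representative_flux(lo, bad), "R1.*s2")
  # flux_table validates midpoint consistency
  expect_error(flux_table(lo, fva_min = lo, fva_max = hi), "midpoint")
  ft <- flux_table(representative_flux(lo, hi), fva_min = lo, fva_max = hi)
  expect_s3_class(ft, "flux_table")
})

test_that("functional-reaction filter removes unannotated and excluded subsystems", {
  fx <- flux_fixture(n_rx = 10)
  sub <- c(R1 = "Fatty acid oxidation", R2 = "Fatty acid oxidation",
           R3 = "Glycolysis", R4 = "Transport reactions",
           R5 = "Transport, mitochondrial", R6 = "Exchange/demand reactions",
           R7 = "Miscellaneous", R8 = "TCA cycle")  # R9, R10 unannotated
  ft <- flux_table(fx$flux, subsystem = sub)
  kept <- filter_functional_reactions(ft)
  expect_identical(sort(rownames(kept$flux)), c("R1", "R2", "R3", "R8"))
  # empty excluded set drops only unannotated reactions
  kept2 <- filter_functional_reactions(ft, excluded_subsystems = character(0))
  expect_identical(sort(rownames(kept2$flux)), paste0("R", 1:8))
  # everything excluded -> empty table, still valid
  all_sub <- stats::setNames(rep("Transport reactions", 10), paste0("R", 1:10))
  empty <- filter_functional_reactions(flux_table(fx$flux, subsystem = all_sub))
  expect_identical(nrow(empty$flux), 0L)
})

test_that("reaction screen flags clear separations and not exact p = 0.1 cases", {
  meta <- sample_metadata(data.frame(
    sample_id = paste0("s", 1:24), group = rep(c("Control", "Tx"), each = 12),
    sex = "F", age_months = "6"))
  flux <- rbind(SEP = c(1:12, 101:112),
                NOPE = c(1, 2, 3, 1, 2, 3, 1.5, 2.5, 3.5, 1.2, 2.2, 3.2,
                         1.1, 2.1, 3.1, 1.3, 2.3, 3.3, 1.4, 2.4, 3.4, 1.6,
                         2.6, 3.6))
  colnames(flux) <- meta$sample_id
  ft <- flux_table(flux, subsystem = c(SEP = "A", NOPE = "A"))
  res <- screen_changed_reactions(ft, meta, "Control", "Tx")
  expect_true(res$changed[res$reaction_id == "SEP"])
  expect_lt(res$p[res$reaction_id == "SEP"], 1e-4)

  # exact small case: [1,2,3] vs [4,5,6] -> p = 0.1 -> not changed
  meta3 <- sample_metadata(data.frame(
    sample_id = paste0("s", 1:6), group = rep(c("Control", "Tx"), each = 3),
    sex = "F", age_months = "6"))
  f3 <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
               dimnames = list("R1", meta3$sample_id))
  res3 <- screen_changed_reactions(flux_table(f3, subsystem = c(R1 = "A")),
                                   meta3, "Control", "Tx")
  expect_equal(res3$p, 0.1)
  expect_equal(res3$p, oracle_mw_exact(c(4, 5, 6), c(1, 2, 3)))
  expect_false(res3$changed)

  # constant-everywhere reaction is never "changed"
  fc <- matrix(5, 1, 6, dimnames = list("R1", meta3$sample_id))
  resc <- screen_changed_reactions(flux_table(fc, subsystem = c(R1 = "A")),
                                   meta3, "Control", "Tx")
  expect_equal(resc$p, 1)
  expect_false(resc$changed)
})

test_that("null reactions are flagged at roughly the nominal rate", {
  set.seed(301)
  meta <- sample_metadata(data.frame(
    sample_id = paste0("s", 1:24), group = rep(c("Control", "Tx"), each = 12),
    sex = "F", age_months = "6"))
  n_rx <- 800
  flux <- matrix(rnorm(n_rx * 24), n_rx, 24,
                 dimnames = list(paste0("R", seq_len(n_rx)), meta$sample_id))
  ft <- flux_table(flux, subsystem = stats::setNames(rep("A", n_rx),
                                                     rownames(flux)))
  res <- screen_changed_reactions(ft, meta, "Control", "Tx")
  expect_lt(abs(mean(res$changed) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rx))
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # N = 10 assessed, K = 4 in subsystem, n = 3 changed, k = 3 -> p = 1/30
  screen <- data.frame(
    reaction_id = paste0("R", 1:10),
    subsystem = rep(c("S1", "S2"), c(4, 6)),
    intervention = "Tx",
    changed = c(TRUE, TRUE, TRUE, FALSE, rep(FALSE, 6)),
    stringsAsFactors = FALSE)
  res <- subsystem_enrichment(screen, "Tx")
  expect_identical(res$subsystem, "S1")  # S2 has no changed reaction
  expect_equal(res$p, 1 / 30)
  expect_equal(res$p, oracle_hyper_upper(10, 4, 3, 3), tolerance = 1e-12)
  expect_identical(c(res$k, res$K, res$n, res$N), c(3L, 4L, 3L, 10L))

  # random parameter sweep against the enumeration oracle
  set.seed(302)
  for (rep in 1:20) {
    N <- sample(5:12, 1); K <- sample(2:(N - 1), 1); n <- sample(1:(N - 1), 1)
    ch <- rep(FALSE, N); ch[sample(N, n)] <- TRUE
    sc <- data.frame(reaction_id = paste0("R", 1:N),
                     subsystem = rep(c("S1", "S2"), c(K, N - K)),
                     intervention = "Tx", changed = ch,
                     stringsAsFactors = FALSE)
    res <- subsystem_enrichment(sc, "Tx")
    k1 <- sum(ch[1:K])
    if (k1 >= 1) {
      expect_equal(res$p[res$subsystem == "S1"],
                   oracle_hyper_upper(N, K, n, k1), tolerance = 1e-10)
    } else {
      expect_false("S1" %in% res$subsystem)
    }
  }

  # no changed reactions -> empty result
  screen0 <- screen; screen0$changed <- FALSE
  expect_identical(nrow(subsystem_enrichment(screen0, "Tx")), 0L)
})

test_that("scaled mean change is centered on control and max-abs scaled", {
  meta <- sample_metadata(data.frame(
    sample_id = paste0("s", 1:8),
    group = rep(c("Control", "I1", "I2", "I3"), each = 2),
    sex = "F", age_months = "6"))
  base <- matrix(0, 2, 8, dimnames = list(c("R1", "R2"), meta$sample_id))
  base["R1", ] <- c(0, 0, 2, 2, -4, -4, 1, 1)  # changes +2, -4, +1
  ft <- flux_table(base, subsystem = c(R1 = "A", R2 = "A"))
  sc <- scaled_mean_change(ft, meta, "Control", c("I1", "I2", "I3"))
  expect_equal(unname(sc["R1", ]), c(0.5, -1.0, 0.25))
  expect_equal(unname(sc["R2", ]), c(0, 0, 0))  # degenerate row stays zero
  expect_true(all(sc >= -1 & sc <= 1))
  # single intervention: any nonzero change maps to +/- 1
  sc1 <- scaled_mean_change(ft, meta, "Control", "I2")
  expect_equal(unname(sc1["R1", ]), -1)
})

test_that("flux TSV and subsystem map round-trip through read_flux", {
  fx <- flux_fixture(n_rx = 4)
  sub <- c(R1 = "A", R2 = "B", R3 = NA, R4 = "Transport reactions")
  ft <- flux_table(fx$flux, subsystem = sub)
  f <- withr::local_tempfile(fileext = ".tsv")
  fs <- withr::local_tempfile(fileext = ".tsv")
  write_flux(ft, f, fs)
  back <- read_flux(f, subsystem_path = fs)
  expect_equal(back$flux, ft$flux, tolerance = 1e-12)
  expect_identical(back$subsystem, ft$subsystem)
})
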