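# Statistical framework over RMS/RCI tables.

# Build a long own+foreign RMS table directly from per-cell value lists:
# values[[consensus]][[group]] = numeric vector of per-sample RMS.
rms_fixture <- function(values, module_id = "M1") {
  rows <- list()
  for (cg in names(values)) {
    for (g in names(values[[cg]])) {
      v <- values[[cg]][[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_s%d", g, seq_along(v)), group = g,
        module_id = module_id, consensus_group = cg, rms = v,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("BH adjustment matches the direct-definition oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  set.seed(201)
  for (rep in 1:200) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    # stable under permutation of the input order
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm])[order(perm)], bh_adjust(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("overall RCI shift uses an exact two-sided Mann-Whitney when possible", {
  rci <- data.frame(group = rep(c("Control", "Tx"), each = 3),
                    module_id = rep(paste0("M", 1:3), 2),
                    rci = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  res <- overall_rci_shift(rci, "Control", "Tx")
  expect_equal(res$p, 0.1)  # 2 / choose(6, 3), verified by enumeration
  expect_equal(res$p, oracle_mw_exact(c(0.4, 0.5, 0.6), c(0.1, 0.2, 0.3)))

  # identical multisets -> no evidence of a shift
  rci2 <- data.frame(group = rep(c("Control", "Tx"), each = 4),
                     module_id = rep(paste0("M", 1:4), 2),
                     rci = rep(c(0.5, 0.6, 0.7, 0.8), 2))
  expect_gt(overall_rci_shift(rci2, "Control", "Tx")$p, 0.5)

  # BH across the interventions compared
  rci3 <- rbind(rci, data.frame(group = "Tx2", module_id = paste0("M", 1:3),
                                rci = c(0.15, 0.25, 0.35)))
  res3 <- overall_rci_shift(rci3, "Control", c("Tx", "Tx2"))
  expect_equal(res3$p_adj, bh_adjust(res3$p))
})

test_that("a +0.2 RCI shift over 164 modules is reliably detected", {
  set.seed(202)
  hits <- 0L
  for (rep in 1:100) {
    base <- runif(164, 0.5, 0.7)
    rci <- data.frame(group = rep(c("Control", "Tx"), each = 164),
                      module_id = rep(paste0("M", 1:164), 2),
                      rci = c(base, pmin(base + 0.2, 1) + rnorm(164, 0, 0.02)))
    if (overall_rci_shift(rci, "Control", "Tx")$p_adj < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("two-group ANOVA equals the squared pooled t and handles degeneracy", {
  set.seed(203)
  x <- rnorm(8); y <- rnorm(8, 1)
  rms <- rms_fixture(list(G1 = list(G1 = x), G2 = list(G2 = y)))
  a <- module_anova(rms)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p, tt$p.value, tolerance = 1e-10)

  # all values identical across groups -> p = 1 by convention
  rms_c <- rms_fixture(list(G1 = list(G1 = rep(0.7, 4)),
                            G2 = list(G2 = rep(0.7, 4))))
  a_c <- module_anova(rms_c)
  expect_equal(a_c$p, 1)
  expect_true(a_c$degenerate)

  # one zero-variance group among varying ones -> F computed normally
  rms_z <- rms_fixture(list(G1 = list(G1 = rep(0.7, 4)),
                            G2 = list(G2 = c(0.6, 0.65, 0.72, 0.8))))
  expect_false(module_anova(rms_z)$degenerate)
})

test_that("ANOVA type-I error is nominal across simulated null modules", {
  set.seed(204)
  n_mod <- 300
  rows <- lapply(seq_len(n_mod), function(k) {
    rms_fixture(list(G1 = list(G1 = rnorm(12, 0.7, 0.05)),
                     G2 = list(G2 = rnorm(12, 0.7, 0.05)),
                     G3 = list(G3 = rnorm(12, 0.7, 0.05))),
                module_id = sprintf("M%03d", k))
  })
  a <- module_anova(do.call(rbind, rows))
  frac <- mean(a$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n_mod))
})

test_that("a strong planted shift gives a tiny ANOVA p", {
  set.seed(205)
  rms <- rms_fixture(list(G1 = list(G1 = rnorm(12, 0.6, 0.05)),
                          G2 = list(G2 = rnorm(12, 0.9, 0.05)),
                          G3 = list(G3 = rnorm(12, 0.6, 0.05)),
                          G4 = list(G4 = rnorm(12, 0.6, 0.05))))
  expect_lt(module_anova(rms)$p, 1e-6)
})

test_that("post-hoc tightening labels follow direction and adjusted p", {
  set.seed(206)
  ctrl <- rnorm(12, 0.6, 0.03)
  rms <- rms_fixture(list(
    Control = list(Control = ctrl),
    ACA = list(ACA = rnorm(12, 0.9, 0.03)),   # tightened
    E2 = list(E2 = rnorm(12, 0.3, 0.03)),     # loosened
    Rapa = list(Rapa = ctrl)))                # identical -> ns, t = 0
  ph <- posthoc_tightening(rms, "Control", c("ACA", "E2", "Rapa"),
                           anova_pass = "M1")
  expect_identical(ph$label[ph$intervention == "ACA"], "tightened")
  expect_identical(ph$label[ph$intervention == "E2"], "loosened")
  expect_identical(ph$label[ph$intervention == "Rapa"], "ns")
  expect_equal(ph$t[ph$intervention == "Rapa"], 0)
  expect_equal(ph$p_adj, bh_adjust(ph$p))

  # degenerate zero-variance cells: exact +0.2 offset -> p -> 0, flagged
  rms_d <- rms_fixture(list(Control = list(Control = rep(0.6, 4)),
                            Tx = list(Tx = rep(0.8, 4))))
  ph_d <- posthoc_tightening(rms_d, "Control", "Tx", anova_pass = "M1")
  expect_equal(ph_d$p, 0)
  expect_true(ph_d$degenerate)
  expect_identical(ph_d$label, "tightened")

  # modules outside the ANOVA gate are not tested
  expect_identical(nrow(posthoc_tightening(rms, "Control", "ACA",
                                           anova_pass = character(0))), 0L)
})

test_that("cross-consensus similarity excludes the consensus group's own samples", {
  set.seed(207)
  # under X's consensus: control low, Y high, X's own rows poisoned with
  # extreme values that must NOT enter the test
  rms <- rms_fixture(list(
    X = list(Control = rnorm(12, 0.55, 0.03),
             Y = rnorm(12, 0.85, 0.03),
             X = rep(99, 12)),
    Y = list(Control = rnorm(12, 0.55, 0.03),
             X = rnorm(12, 0.55, 0.03),
             Y = rep(99, 12))))
  res <- cross_consensus_similarity(rms, "Control", c("X", "Y"),
                                    consensus_groups = c("X", "Y"))
  expect_identical(nrow(res), 2L)  # (X cons, Y cmp) and (Y cons, X cmp)
  hy <- res[res$consensus_group == "X" & res$intervention == "Y", ]
  expect_identical(hy$label, "higher")
  expect_true(all(res$mean_control < 1))  # poisoned rows excluded
  hx <- res[res$consensus_group == "Y" & res$intervention == "X", ]
  expect_identical(hx$label, "ns")

  expect_error(cross_consensus_similarity(rms, "Control", c("X", "Y"),
                                          consensus_groups = "Control"),
               "consensus")
})

test_that("similarity has a nominal false-positive rate under the null", {
  set.seed(208)
  n_mod <- 300
  labs <- character(0)
  for (k in seq_len(n_mod)) {
    rms <- rms_fixture(list(
      X = list(Control = rnorm(10, 0.6, 0.05), Y = rnorm(10, 0.6, 0.05),
               X = rnorm(10, 0.9, 0.02))),
      module_id = sprintf("M%03d", k))
    res <- cross_consensus_similarity(rms, "Control", "Y",
                                      consensus_groups = "X")
    labs <- c(labs, res$label)
  }
  expect_lt(mean(labs != "ns"), 0.05 + 3 * sqrt(0.05 * 0.95 / n_mod))
})

test_that("consistent tightening summary does set algebra and similarity gating", {
  ph <- data.frame(
    module_id = rep(c("A", "B", "C"), each = 3),
    intervention = rep(c("I1", "I2", "I3"), 3),
    label = c("tightened", "tightened", "ns",      # A: I1, I2
              "tightened", "tightened", "tightened",  # B: all three
              "ns", "tightened", "ns"),            # C: I2
    stringsAsFactors = FALSE)
  sim <- data.frame(
    module_id = rep("B", 6),
    consensus_group = rep(c("I1", "I2", "I3"), each = 2),
    intervention = c("I2", "I3", "I1", "I3", "I1", "I2"),
    label = "higher", stringsAsFactors = FALSE)
  s <- consistent_tightening_summary(ph, sim, c("I1", "I2", "I3"))
  expect_identical(s$tightened_by$I1, c("A", "B"))
  expect_identical(s$tightened_all, "B")
  expect_identical(s$tightened_all_similar, "B")
  # one dissimilar cell removes the module from the similar set
  sim2 <- sim; sim2$label[4] <- "lower"
  s2 <- consistent_tightening_summary(ph, sim2, c("I1", "I2", "I3"))
  expect_identical(s2$tightened_all, "B")
  expect_identical(s2$tightened_all_similar, character(0))

  empty <- consistent_tightening_summary(ph[0, ], NULL, c("I1", "I2"))
  expect_identical(empty$tightened_all, character(0))
  expect_identical(unname(empty$counts["n_tightened_all"]), 0L)
})
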