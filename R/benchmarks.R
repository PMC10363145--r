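## Calibration and recovery benchmarks: the package's own evaluation of its
## statistics on generator data with known truth. These back the analysis
## drivers and the acceptance checks.

#' Expected own-consensus RCI under the i.i.d. null
#'
#' For i.i.d. continuous data, each analyte pair's majority template matches
#' `max(K, n - K)` of the group's `n` samples, with `K ~ Binomial(n, 1/2)`;
#' by linearity the expected own-consensus RCI is `E[max(K, n - K)] / n`
#' for any module size. Evaluates the closed form by exact summation
#' (0.75 at n = 3, 0.6875 at n = 4, 0.6127929... at n = 12).
#'
#' @param n Group size.
#' @return Expected RCI under the null.
#' @export
expected_null_rci <- function(n) {
  k <- 0:n
  sum(pmax(k, n - k) * stats::dbinom(k, n, 0.5)) / n
}

#' Monte Carlo own-consensus RCI of i.i.d. Gaussian modules
#'
#' Generates `n_modules` pure-noise modules (spacing 0) for a single group
#' of `n_samples`, runs the DIRAC scoring, and summarizes the own-consensus
#' RCI distribution for comparison against [expected_null_rci()].
#'
#' @param n_samples Group size.
#' @param n_modules Number of simulated modules.
#' @param module_size Analytes per module.
#' @param seed Integer seed.
#' @return List: `mean`, `se` (Monte Carlo standard error), `expected`,
#'   `n_modules`.
#' @export
simulate_null_rci <- function(n_samples, n_modules = 10000L,
                              module_size = 5L, seed = 1L) {
  sigma <- c(G1 = 1)
  consensus <- c(G1 = "O1")
  specs <- lapply(seq_len(n_modules), function(k) {
    module_spec(sprintf("M%05d", k), module_size, delta = 0,
                sigma = sigma, consensus = consensus)
  })
  s <- generate_abundance("G1", n_samples, specs, seed = seed)
  d <- dirac_rms(s$abundance, s$metadata, s$modules)
  list(mean = mean(d$rci$rci),
       se = stats::sd(d$rci$rci) / sqrt(nrow(d$rci)),
       expected = expected_null_rci(n_samples),
       n_modules = nrow(d$rci))
}

#' ANOVA calibration under the exchangeable global null
#'
#' Repeatedly generates the global-null study (all groups share one
#' consensus ordering and noise level; no planted effects), runs DIRAC and
#' the per-module ANOVA, and collects the null p-value behavior: nominal
#' rejection rates, Benjamini-Hochberg positive counts, and the first
#' replicate's raw p-values for a uniformity test.
#'
#' @param n_replicates Number of independent replicate studies.
#' @param n_modules Modules per study.
#' @param groups Group labels.
#' @param n_per_group Samples per group.
#' @param module_size,delta,sigma Generator parameters of the shared-null
#'   modules. The default noise scale (0.7, adjacent-pair inversion
#'   probability ~0.16) keeps genuine shared structure in every group:
#'   that is the regime where consensus templates are pinned to the true
#'   ordering and the F statistic's null premise holds. With weak or
#'   absent structure the own-template fit absorbs group-level
#'   fluctuation and the ANOVA becomes conservative (see the methods
#'   vignette).
#' @param alpha Nominal level for the rejection-rate summary.
#' @param seed Integer seed.
#' @return List: `p_first` (first replicate's p-values),
#'   `rejection_rates` and `fdr_positive_counts` (per replicate),
#'   `rejection_rate` and `fdr_positive_mean` (means).
#' @export
anova_null_calibration <- function(n_replicates = 50L, n_modules = 500L,
                                   groups = c("Control", "ACA", "17aE2", "Rapa"),
                                   n_per_group = 12L, module_size = 8L,
                                   delta = 1, sigma = 0.7, alpha = 0.05,
                                   seed = 1L) {
  sg <- stats::setNames(rep(sigma, length(groups)), groups)
  cons <- stats::setNames(rep("O1", length(groups)), groups)
  specs <- lapply(seq_len(n_modules), function(k) {
    module_spec(sprintf("M%04d", k), module_size, delta = delta,
                sigma = sg, consensus = cons)
  })
  rates <- numeric(n_replicates)
  fdr_counts <- integer(n_replicates)
  p_first <- NULL
  for (r in seq_len(n_replicates)) {
    s <- generate_abundance(groups, n_per_group, specs,
                            seed = seed + r - 1L)
    d <- dirac_rms(s$abundance, s$metadata, s$modules)
    a <- module_anova(d$rms)
    if (r == 1L) p_first <- a$p
    rates[r] <- mean(a$p < alpha)
    fdr_counts[r] <- sum(a$p_adj < alpha)
  }
  list(p_first = p_first, rejection_rates = rates,
       fdr_positive_counts = fdr_counts,
       rejection_rate = mean(rates),
       fdr_positive_mean = mean(fdr_counts))
}

#' Null false-positive rate of the flux screen
#'
#' Generates a flux study with no planted shifts, applies the
#' functional-reaction filter and the Mann-Whitney screen, and returns the
#' fraction of (reaction, intervention) cells flagged at the nominal
#' threshold - expected to sit near the nominal level.
#'
#' @param n_reactions Functional reactions to simulate (spread over eight
#'   subsystems).
#' @param groups Group labels (first = control).
#' @param n_per_group Samples per group.
#' @param alpha Nominal screening threshold.
#' @param seed Integer seed.
#' @return List: `changed_rate`, `n_cells`.
#' @export
flux_null_screen_rate <- function(n_reactions = 800L,
                                  groups = c("Control", "ACA", "17aE2", "Rapa"),
                                  n_per_group = 12L, alpha = 0.05,
                                  seed = 1L) {
  per <- ceiling(n_reactions / 8L)
  fl <- generate_flux(groups, n_per_group,
                      subsystems = stats::setNames(rep(per, 8L),
                                                   sprintf("Subsystem %02d", 1:8)),
                      shifts = list(), seed = seed)
  kept <- filter_functional_reactions(fl$flux)
  screen <- screen_changed_reactions(kept, fl$metadata, groups[1L],
                                     groups[-1L], alpha = alpha)
  list(changed_rate = mean(screen$changed), n_cells = nrow(screen))
}

#' Recovery benchmark on the reference synthetic scenario
#'
#' Runs the full pipeline (with the exchangeability-preserving
#' normalization, see [preprocess_abundance()]) on repeated draws of
#' [simulate_intervention_study()] and scores it against the planted truth:
#' sensitivity and empirical false discovery rate of the recovered
#' "tightened by all interventions, similar" module set, and the accuracy
#' of the similarity classifier (shared-consensus cells labeled `"higher"`,
#' distinct-consensus cells not).
#'
#' @param n_seeds Number of independent scenario draws.
#' @param seed_base Seed of the first draw (draw k uses `seed_base + k - 1`).
#' @param ... Passed to [simulate_intervention_study()].
#' @return List: per-seed `sensitivity` and `fdr` vectors with their means,
#'   pooled `similarity_accuracy_shared` / `similarity_accuracy_distinct`,
#'   and `n_seeds`.
#' @export
recovery_benchmark <- function(n_seeds = 25L, seed_base = 1L, ...) {
  sens <- numeric(n_seeds)
  fdr <- numeric(n_seeds)
  shared_hits <- shared_tot <- distinct_hits <- distinct_tot <- 0L
  for (k in seq_len(n_seeds)) {
    s <- simulate_intervention_study(seed = seed_base + k - 1L, ...)
    r <- run_pipeline(s$abundance, s$metadata, s$modules,
                      control = s$control,
                      interventions = s$interventions,
                      control_reference = FALSE)
    truth <- s$truth$tightened_all_similar
    rec <- r$summary$tightened_all_similar
    sens[k] <- if (length(truth)) mean(truth %in% rec) else NA_real_
    fdr[k] <- if (length(rec)) mean(!rec %in% truth) else 0
    sim <- r$similarity
    sh <- sim$module_id %in% s$truth$classes$tight_all_shared
    di <- sim$module_id %in% s$truth$classes$tight_all_distinct
    shared_hits <- shared_hits + sum(sim$label[sh] == "higher")
    shared_tot <- shared_tot + sum(sh)
    distinct_hits <- distinct_hits + sum(sim$label[di] != "higher")
    distinct_tot <- distinct_tot + sum(di)
  }
  list(sensitivity = sens, fdr = fdr,
       sensitivity_mean = mean(sens, na.rm = TRUE),
       fdr_mean = mean(fdr),
       similarity_accuracy_shared = shared_hits / shared_tot,
       similarity_accuracy_distinct = distinct_hits / distinct_tot,
       n_seeds = n_seeds)
}
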