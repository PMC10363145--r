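## Statistics over RMS/RCI tables: the overall tightening shift, per-module
## intervention effects, post-hoc tightened/loosened calls, and
## cross-consensus similarity classification. All multiple-testing
## adjustment is Benjamini-Hochberg within explicit families that mirror
## the analysis design:
##  - overall shift: across the interventions compared;
##  - module ANOVA: across all tested modules (or modules x datasets when
##    two omic layers share the family);
##  - post hoc tightening: per module, across the intervention comparisons;
##  - similarity: per module, across (comparisons x consensus groups).
## Flat BH over partially dependent GO modules is conservative (inflates
## false negatives, not false positives); the package keeps it.

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: monotone-enforced, capped at 1, stable under
#' permutation of the input order.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) fail("p-values must be numeric")
  bad <- !is.na(pvalues) & (pvalues < 0 | pvalues > 1)
  if (any(bad)) {
    fail("p-values outside [0, 1]: %s",
         paste(format(pvalues[bad]), collapse = ", "))
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Mann-Whitney U test wrapper: exact p when the combined sample is small
# and tie-free, otherwise normal approximation with tie correction and
# continuity correction.
mw_test <- function(x, y, exact_max_n = 16L) {
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= exact_max_n
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(ht$statistic), p = min(1, ht$p.value), exact = exact)
}

# Welch two-sample t with the degenerate zero-variance convention:
# if both cells are (numerically) constant, p = 1 when the means agree and
# p = 0 when they differ, flagged - a module is never silently dropped.
welch_test <- function(x, y) {
  degenerate <- stats::sd(x) == 0 && stats::sd(y) == 0
  if (degenerate) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                p = if (eq) 1 else 0, degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
}

# One-way fixed-effects ANOVA of values ~ group; all-identical values give
# p = 1 by convention (no evidence of any effect), flagged.
anova_test <- function(values, group) {
  if (length(unique(values)) == 1L) {
    return(list(F = 0, p = 1, degenerate = TRUE))
  }
  ht <- tryCatch(stats::oneway.test(values ~ factor(group), var.equal = TRUE),
                 error = function(e) NULL)
  if (is.null(ht) || is.na(ht$p.value)) {
    return(list(F = NA_real_, p = 1, degenerate = TRUE))
  }
  list(F = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
}

# Pull own-consensus RMS rows: sample group == consensus group.
own_consensus_rms <- function(rms) {
  rms[rms$group == rms$consensus_group, , drop = FALSE]
}

#' Overall RCI shift between control and each intervention
#'
#' Tests whether an intervention shifts the distribution of module RCIs
#' relative to control: a two-sided Mann-Whitney U test over modules for
#' each intervention, BH-adjusted across the interventions compared.
#'
#' @param rci RCI data.frame from [dirac_rms()] (columns group, module_id,
#'   rci), covering the same module set for all groups.
#' @param control Control group label.
#' @param interventions Character vector of intervention group labels.
#' @return data.frame (intervention, U, p, p_adj, median_control,
#'   median_intervention).
#' @export
overall_rci_shift <- function(rci, control, interventions) {
  x <- rci$rci[rci$group == control]
  if (length(x) < 2L) fail("control has < 2 module RCIs")
  rows <- lapply(interventions, function(g) {
    y <- rci$rci[rci$group == g]
    if (length(y) < 2L) fail("group '%s' has < 2 module RCIs", g)
    if (length(y) != length(x)) {
      fail("group '%s' has %d module RCIs but control has %d; same module set required",
           g, length(y), length(x))
    }
    mt <- mw_test(y, x)
    data.frame(intervention = g, U = mt$U, p = mt$p,
               median_control = stats::median(x),
               median_intervention = stats::median(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out[, c("intervention", "U", "p", "p_adj",
          "median_control", "median_intervention")]
}

#' Per-module intervention effect on rank conservation
#'
#' One-way fixed-effects ANOVA (RMS ~ group) on own-consensus rank matching
#' scores, per module, across all supplied groups (control plus the
#' interventions); BH adjustment across all tested modules. For designs
#' pooling several datasets into one family, concatenate their RMS tables
#' (module ids made unique per dataset) before calling.
#'
#' @param rms Long RMS data.frame from [dirac_rms()]; only own-consensus
#'   rows are used.
#' @param groups Groups entering the ANOVA (default: all in the table).
#' @return data.frame (module_id, F, p, p_adj, degenerate).
#' @export
module_anova <- function(rms, groups = NULL) {
  own <- own_consensus_rms(rms)
  if (!is.null(groups)) own <- own[own$group %in% groups, , drop = FALSE]
  if (!nrow(own)) fail("no own-consensus RMS rows for the requested groups")
  cnt <- table(own$group, own$module_id)
  if (any(cnt < 2L)) {
    fail("every group needs >= 2 own-consensus samples per module")
  }
  by_mod <- split(own, own$module_id)
  rows <- lapply(by_mod, function(d) {
    at <- anova_test(d$rms, d$group)
    data.frame(module_id = d$module_id[1L], F = at$F, p = at$p,
               degenerate = at$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- bh_adjust(out$p)
  if (any(out$degenerate)) {
    dlog("module_anova: %d degenerate module(s) (identical values) given p = 1",
         sum(out$degenerate))
  }
  out[, c("module_id", "F", "p", "p_adj", "degenerate")]
}

#' Post-hoc tightened/loosened calls per module and intervention
#'
#' For modules passing the ANOVA stage, compares each intervention's
#' own-consensus RMS against control with a two-sided Welch t-test, BH
#' adjusted per module across the intervention comparisons. A module is
#' *tightened* by an intervention if the adjusted p is below `alpha` and
#' the intervention mean exceeds the control mean; *loosened* in the
#' opposite direction.
#'
#' @param rms Long RMS data.frame from [dirac_rms()].
#' @param control Control group label.
#' @param interventions Intervention group labels.
#' @param anova_pass Module ids that passed the ANOVA FDR gate; only these
#'   are tested (pass all module ids to skip the gate for diagnostics).
#' @param alpha Significance threshold on the adjusted p (default 0.05).
#' @return data.frame (module_id, intervention, t, p, p_adj, mean_control,
#'   mean_intervention, direction, label, degenerate); `label` is
#'   `"tightened"`, `"loosened"` or `"ns"`.
#' @export
posthoc_tightening <- function(rms, control, interventions, anova_pass,
                               alpha = 0.05) {
  check_alpha(alpha)
  own <- own_consensus_rms(rms)
  own <- own[own$module_id %in% anova_pass, , drop = FALSE]
  if (!nrow(own)) {
    return(data.frame(module_id = character(0), intervention = character(0),
                      t = numeric(0), p = numeric(0), p_adj = numeric(0),
                      mean_control = numeric(0),
                      mean_intervention = numeric(0),
                      direction = character(0), label = character(0),
                      degenerate = logical(0), stringsAsFactors = FALSE))
  }
  by_mod <- split(own, own$module_id)
  rows <- lapply(by_mod, function(d) {
    x <- d$rms[d$group == control]
    if (length(x) < 2L) fail("control has < 2 samples in module %s", d$module_id[1L])
    per_int <- lapply(interventions, function(g) {
      y <- d$rms[d$group == g]
      if (length(y) < 2L) fail("group '%s' has < 2 samples in module %s",
                               g, d$module_id[1L])
      wt <- welch_test(y, x)
      data.frame(module_id = d$module_id[1L], intervention = g,
                 t = wt$t, p = wt$p, mean_control = mean(x),
                 mean_intervention = mean(y),
                 degenerate = wt$degenerate, stringsAsFactors = FALSE)
    })
    mod <- do.call(rbind, per_int)
    mod$p_adj <- bh_adjust(mod$p)  # family: the intervention comparisons
    mod
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$direction <- ifelse(out$mean_intervention > out$mean_control, "up",
                          ifelse(out$mean_intervention < out$mean_control,
                                 "down", "none"))
  out$label <- ifelse(out$p_adj < alpha & out$direction == "up", "tightened",
                      ifelse(out$p_adj < alpha & out$direction == "down",
                             "loosened", "ns"))
  if (any(out$degenerate)) {
    dlog("posthoc_tightening: %d degenerate zero-variance comparison(s)",
         sum(out$degenerate))
  }
  out[, c("module_id", "intervention", "t", "p", "p_adj", "mean_control",
          "mean_intervention", "direction", "label", "degenerate")]
}

#' Cross-consensus similarity of module regulation
#'
#' Asks whether an intervention's module pattern matches another group's
#' consensus better than control does: for each consensus group X and each
#' intervention Y != X, a two-sided Welch t-test of control vs Y on RMS
#' under X's template. The consensus group's own samples are excluded from
#' both sides (their RMS under their own template follows a different,
#' optimistically biased distribution), so X may be neither `control` nor a
#' compared intervention in any single test. BH adjustment is per module
#' across all (consensus x comparison) cells. Labels: `"higher"` (the
#' intervention matches X's consensus better than control - similarly
#' changed), `"lower"` (dissimilarly changed), `"ns"`.
#'
#' @param rms Long RMS data.frame from [dirac_rms()] including rows under
#'   every requested consensus group.
#' @param control Control group label.
#' @param interventions Intervention group labels (compared against
#'   control).
#' @param consensus_groups Consensus groups X to assess under; must not
#'   include `control`. Defaults to `interventions`.
#' @param alpha Threshold on adjusted p (default 0.05).
#' @return data.frame (module_id, consensus_group, intervention, t, p,
#'   p_adj, mean_control, mean_intervention, label, degenerate).
#' @export
cross_consensus_similarity <- function(rms, control, interventions,
                                       consensus_groups = NULL,
                                       alpha = 0.05) {
  check_alpha(alpha)
  if (is.null(consensus_groups)) consensus_groups <- interventions
  if (control %in% consensus_groups) {
    fail("control group '%s' cannot serve as a similarity consensus group (it is a compared group in every test)",
         control)
  }
  cells <- expand.grid(consensus_group = consensus_groups,
                       intervention = interventions,
                       stringsAsFactors = FALSE)
  cells <- cells[cells$consensus_group != cells$intervention, , drop = FALSE]
  if (!nrow(cells)) fail("no (consensus, intervention) cells to test")
  by_mod <- split(rms, rms$module_id)
  rows <- lapply(by_mod, function(d) {
    mod <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
      X <- cells$consensus_group[k]
      Y <- cells$intervention[k]
      under_x <- d[d$consensus_group == X & d$group != X, , drop = FALSE]
      x <- under_x$rms[under_x$group == control]
      y <- under_x$rms[under_x$group == Y]
      if (length(x) < 2L || length(y) < 2L) {
        fail("module %s: < 2 samples for control or '%s' under consensus '%s'",
             d$module_id[1L], Y, X)
      }
      wt <- welch_test(y, x)
      data.frame(module_id = d$module_id[1L], consensus_group = X,
                 intervention = Y, t = wt$t, p = wt$p,
                 mean_control = mean(x), mean_intervention = mean(y),
                 degenerate = wt$degenerate, stringsAsFactors = FALSE)
    }))
    mod$p_adj <- bh_adjust(mod$p)  # family: comparisons x consensus groups
    mod
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$label <- ifelse(out$p_adj < alpha &
                        out$mean_intervention > out$mean_control, "higher",
                      ifelse(out$p_adj < alpha &
                               out$mean_intervention < out$mean_control,
                             "lower", "ns"))
  out[, c("module_id", "consensus_group", "intervention", "t", "p", "p_adj",
          "mean_control", "mean_intervention", "label", "degenerate")]
}

#' Cross-intervention tightening summary
#'
#' Combines the per-intervention tightened sets into Venn-style
#' intersections and, using the similarity labels, identifies the modules
#' tightened by every intervention whose pattern is shared: a module is
#' *consistently tightened, similar* iff it is tightened by all
#' interventions and every cross-consensus cell among the interventions is
#' labeled `"higher"`.
#'
#' @param posthoc Output of [posthoc_tightening()].
#' @param similarity Output of [cross_consensus_similarity()] (optional; if
#'   `NULL` the similarity-based sets are empty).
#' @param interventions Intervention labels defining "all".
#' @return List: `tightened_by` (named list of module-id vectors),
#'   `loosened_by`, `tightened_all` (intersection), `tightened_all_similar`,
#'   `counts` (named integer summary).
#' @export
consistent_tightening_summary <- function(posthoc, similarity = NULL,
                                          interventions = NULL) {
  if (is.null(interventions)) interventions <- unique(posthoc$intervention)
  tightened_by <- lapply(interventions, function(g) {
    sort(posthoc$module_id[posthoc$intervention == g &
                             posthoc$label == "tightened"])
  })
  names(tightened_by) <- interventions
  loosened_by <- lapply(interventions, function(g) {
    sort(posthoc$module_id[posthoc$intervention == g &
                             posthoc$label == "loosened"])
  })
  names(loosened_by) <- interventions
  tightened_all <- if (length(tightened_by)) {
    Reduce(intersect, tightened_by)
  } else character(0)
  tightened_all_similar <- character(0)
  if (!is.null(similarity) && length(tightened_all)) {
    tightened_all_similar <- Filter(function(mid) {
      cells <- similarity[similarity$module_id == mid &
                            similarity$consensus_group %in% interventions &
                            similarity$intervention %in% interventions, ,
                          drop = FALSE]
      nrow(cells) > 0L && all(cells$label == "higher")
    }, tightened_all)
  }
  list(tightened_by = tightened_by,
       loosened_by = loosened_by,
       tightened_all = tightened_all,
       tightened_all_similar = as.character(tightened_all_similar),
       counts = c(n_tested = length(unique(posthoc$module_id)),
                  stats::setNames(lengths(tightened_by),
                                  paste0("tightened_", names(tightened_by))),
                  n_tightened_all = length(tightened_all),
                  n_tightened_all_similar = length(tightened_all_similar)))
}
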