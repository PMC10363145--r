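## Downstream metabolic-flux analysis. Input is a predicted flux table
## (reactions x samples) - either given directly or as the midpoint of
## per-reaction flux variability (FVA) ranges - with a reaction -> subsystem
## map. Pseudo-reactions (unannotated, exchange/demand, miscellaneous,
## transport) are removed; the remaining functional reactions are screened
## per intervention with Mann-Whitney tests at nominal p < 0.05 (a
## deliberately unadjusted screening stage); the subsystems overrepresented
## among the screened reactions carry the FDR-level inference.

# Subsystem categories excluded from functional-reaction analysis; matched
# case-insensitively as label prefixes so "Transport reactions",
# "Transport, mitochondrial" etc. are all caught.
DEFAULT_EXCLUDED_SUBSYSTEMS <- c("exchange/demand", "exchange", "demand",
                                 "miscellaneous", "transport")

#' Construct a flux table
#'
#' @param flux Numeric matrix (reactions x samples) with unique dimnames.
#' @param subsystem Named character vector mapping reaction ids to
#'   subsystem labels; reactions absent from the map (or mapped to `NA`)
#'   count as unannotated.
#' @param fva_min,fva_max Optional matrices of the same shape giving the
#'   FVA range; if present, `fva_min <= fva_max` elementwise must hold and
#'   `flux` must equal their midpoint.
#' @return Object of class `flux_table`.
#' @export
flux_table <- function(flux, subsystem = NULL, fva_min = NULL, fva_max = NULL) {
  if (!is.matrix(flux) || !is.numeric(flux)) fail("flux must be a numeric matrix")
  if (nrow(flux) > 0L && ncol(flux) > 0L &&
      (is.null(rownames(flux)) || is.null(colnames(flux)))) {
    fail("flux matrix needs reaction rownames and sample colnames")
  }
  if (anyDuplicated(rownames(flux)) || anyDuplicated(colnames(flux))) {
    fail("duplicate reaction or sample identifiers in flux table")
  }
  if (!is.null(fva_min) || !is.null(fva_max)) {
    if (is.null(fva_min) || is.null(fva_max)) {
      fail("fva_min and fva_max must be given together")
    }
    if (!identical(dim(fva_min), dim(flux)) ||
        !identical(dim(fva_max), dim(flux))) {
      fail("FVA matrices must match the flux matrix shape")
    }
    bad <- which(fva_min > fva_max, arr.ind = TRUE)
    if (nrow(bad)) {
      fail("fva_min > fva_max at reaction '%s', sample '%s'",
           rownames(flux)[bad[1L, 1L]], colnames(flux)[bad[1L, 2L]])
    }
    if (max(abs(flux - (fva_min + fva_max) / 2)) > 1e-8) {
      fail("flux must equal the FVA midpoint (fva_min + fva_max) / 2")
    }
  }
  sub <- rep(NA_character_, nrow(flux))
  names(sub) <- rownames(flux)
  if (!is.null(subsystem)) {
    known <- intersect(names(subsystem), rownames(flux))
    sub[known] <- as.character(subsystem[known])
  }
  structure(list(flux = flux, subsystem = sub,
                 fva_min = fva_min, fva_max = fva_max),
            class = "flux_table")
}

#' @export
print.flux_table <- function(x, ...) {
  cat(sprintf("flux_table: %d reactions x %d samples (%d unannotated)\n",
              nrow(x$flux), ncol(x$flux), sum(is.na(x$subsystem))))
  invisible(x)
}

#' Representative flux from FVA bounds
#'
#' The midpoint `(min + max) / 2` of each reaction's flux variability range
#' is used as its predicted flux value.
#'
#' @param fva_min,fva_max Numeric matrices (reactions x samples),
#'   `fva_min <= fva_max` elementwise.
#' @return Numeric matrix of the same shape.
#' @export
representative_flux <- function(fva_min, fva_max) {
  if (!identical(dim(fva_min), dim(fva_max))) {
    fail("fva_min and fva_max shapes differ")
  }
  bad <- which(fva_min > fva_max, arr.ind = TRUE)
  if (nrow(bad)) {
    rn <- rownames(fva_min)
    cn <- colnames(fva_min)
    fail("fva_min > fva_max at row %s, column %s",
         if (is.null(rn)) bad[1L, 1L] else rn[bad[1L, 1L]],
         if (is.null(cn)) bad[1L, 2L] else cn[bad[1L, 2L]])
  }
  (fva_min + fva_max) / 2
}

#' Drop pseudo- and hard-to-interpret reactions
#'
#' Removes reactions without a subsystem annotation (e.g., the biomass
#' pseudo-reaction) and reactions whose subsystem falls in the excluded
#' categories (by default exchange/demand, miscellaneous and transport;
#' matched case-insensitively as label prefixes). Only the remaining
#' functional reactions are assessed downstream.
#'
#' @param ft A [flux_table()].
#' @param excluded_subsystems Character vector of excluded category
#'   prefixes.
#' @return A [flux_table()] with only functional reactions (may be empty,
#'   which is flagged).
#' @export
filter_functional_reactions <- function(ft, excluded_subsystems = DEFAULT_EXCLUDED_SUBSYSTEMS) {
  sub <- ft$subsystem
  unann <- is.na(sub)
  excl <- !unann & Reduce(`|`, lapply(excluded_subsystems, function(p) {
    startsWith(tolower(trimws(sub)), tolower(p))
  }), rep(FALSE, length(sub)))
  keep <- !unann & !excl
  dlog("filter_functional_reactions: %d -> %d reactions (%d unannotated, %d in excluded subsystems)",
       length(keep), sum(keep), sum(unann), sum(excl))
  if (!any(keep)) dlog("filter_functional_reactions: no functional reaction remains")
  flux_table(ft$flux[keep, , drop = FALSE],
             subsystem = sub[keep],
             fva_min = if (!is.null(ft$fva_min)) ft$fva_min[keep, , drop = FALSE],
             fva_max = if (!is.null(ft$fva_max)) ft$fva_max[keep, , drop = FALSE])
}

#' Screen reactions for flux changes per intervention
#'
#' Per reaction and intervention, a two-sided Mann-Whitney U test of the
#' flux distribution against control. A reaction is flagged *changed* at
#' nominal p < `alpha` (explicitly unadjusted: this is a screening stage;
#' FDR control happens at the subsystem-enrichment level).
#'
#' @param ft A functional [flux_table()] (see
#'   [filter_functional_reactions()]).
#' @param meta [sample_metadata()] covering the flux samples.
#' @param control Control group label; every tested group needs >= 3
#'   samples.
#' @param interventions Intervention labels.
#' @param alpha Nominal screening threshold (default 0.05).
#' @return data.frame (reaction_id, subsystem, intervention, U, p, changed,
#'   mean_control, mean_intervention).
#' @export
screen_changed_reactions <- function(ft, meta, control, interventions,
                                     alpha = 0.05) {
  check_alpha(alpha)
  meta <- match_metadata(ft$flux, meta)
  for (g in c(control, interventions)) {
    if (sum(meta$group == g) < 3L) {
      fail("group '%s' has %d sample(s); need >= 3", g, sum(meta$group == g))
    }
  }
  ctrl_cols <- meta$sample_id[meta$group == control]
  rows <- lapply(rownames(ft$flux), function(r) {
    x <- ft$flux[r, ctrl_cols]
    do.call(rbind, lapply(interventions, function(g) {
      y <- ft$flux[r, meta$sample_id[meta$group == g]]
      if (length(unique(c(x, y))) == 1L) {
        # constant everywhere: no distributional difference by definition
        return(data.frame(reaction_id = r, subsystem = ft$subsystem[[r]],
                          intervention = g, U = length(x) * length(y) / 2,
                          p = 1, changed = FALSE, mean_control = mean(x),
                          mean_intervention = mean(y),
                          stringsAsFactors = FALSE))
      }
      mt <- mw_test(y, x)
      data.frame(reaction_id = r, subsystem = ft$subsystem[[r]],
                 intervention = g, U = mt$U, p = mt$p,
                 changed = mt$p < alpha, mean_control = mean(x),
                 mean_intervention = mean(y), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  for (g in interventions) {
    dlog("screen_changed_reactions: %s: %d of %d reactions changed at nominal p < %g",
         g, sum(out$changed[out$intervention == g]), nrow(ft$flux), alpha)
  }
  out
}

#' Subsystem overrepresentation among changed reactions
#'
#' For one intervention's screen, tests each subsystem containing at least
#' one changed reaction for enrichment with a one-sided hypergeometric
#' (upper-tail) test: universe = all assessed functional reactions, K =
#' subsystem size in the universe, n = changed reactions, k = changed in
#' the subsystem. BH adjustment across exactly the tested subsystems. No
#' changed reactions yields an empty result.
#'
#' @param screen Output of [screen_changed_reactions()] restricted to (or
#'   filtered by) one intervention.
#' @param intervention Which intervention's screen to use.
#' @return data.frame (subsystem, k, K, n, N, p, p_adj), ordered by p.
#' @export
subsystem_enrichment <- function(screen, intervention) {
  d <- screen[screen$intervention == intervention, , drop = FALSE]
  if (!nrow(d)) fail("no screen rows for intervention '%s'", intervention)
  N <- nrow(d)
  n <- sum(d$changed)
  if (n == 0L) {
    dlog("subsystem_enrichment: no changed reaction for %s; empty result",
         intervention)
    return(data.frame(subsystem = character(0), k = integer(0),
                      K = integer(0), n = integer(0), N = integer(0),
                      p = numeric(0), p_adj = numeric(0),
                      stringsAsFactors = FALSE))
  }
  tested <- sort(unique(d$subsystem[d$changed]))
  rows <- lapply(tested, function(s) {
    K <- sum(d$subsystem == s)
    k <- sum(d$changed & d$subsystem == s)
    # upper tail P(X >= k), X ~ Hypergeometric(N, K, n)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(subsystem = s, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p, out$subsystem), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Control-centered, max-abs-scaled mean flux changes
#'
#' For visualization-style summaries: per reaction, the group mean flux of
#' each intervention minus the control group mean, then each reaction's row
#' scaled by its maximum absolute change across interventions, so entries
#' lie in [-1, 1] and each non-degenerate row touches +/-1. Rows with no
#' change in any intervention stay zero (no division).
#'
#' @param ft A [flux_table()].
#' @param meta [sample_metadata()].
#' @param control Control group label.
#' @param interventions Intervention labels.
#' @return Numeric matrix (reactions x interventions) in [-1, 1].
#' @export
scaled_mean_change <- function(ft, meta, control, interventions) {
  if (!length(interventions)) fail("need >= 1 intervention")
  meta <- match_metadata(ft$flux, meta)
  ctrl_mean <- rowMeans(ft$flux[, meta$sample_id[meta$group == control],
                                drop = FALSE])
  d <- vapply(interventions, function(g) {
    rowMeans(ft$flux[, meta$sample_id[meta$group == g], drop = FALSE]) -
      ctrl_mean
  }, numeric(nrow(ft$flux)))
  d <- matrix(d, nrow = nrow(ft$flux),
              dimnames = list(rownames(ft$flux), interventions))
  scale <- apply(abs(d), 1L, max)
  nz <- scale > 0
  d[nz, ] <- d[nz, , drop = FALSE] / scale[nz]
  d
}

#' Read a flux table (and optional subsystem map) from TSV
#'
#' @param path Flux matrix TSV: reactions as rows, identifier first column.
#' @param subsystem_path Optional TSV with columns `reaction_id`,
#'   `subsystem` (empty subsystem = unannotated).
#' @param fva_min_path,fva_max_path Optional FVA bound matrices; when
#'   given, the flux is their midpoint and `path` may be `NULL`.
#' @return A [flux_table()].
#' @export
read_flux <- function(path, subsystem_path = NULL,
                      fva_min_path = NULL, fva_max_path = NULL) {
  read_mat <- function(p) ab_values(read_abundance(p))
  fmin <- if (!is.null(fva_min_path)) read_mat(fva_min_path)
  fmax <- if (!is.null(fva_max_path)) read_mat(fva_max_path)
  flux <- if (!is.null(path)) read_mat(path) else representative_flux(fmin, fmax)
  sub <- NULL
  if (!is.null(subsystem_path)) {
    sdf <- utils::read.table(subsystem_path, header = TRUE, sep = "\t",
                             colClasses = "character", check.names = FALSE,
                             quote = "", comment.char = "",
                             na.strings = c("", "NA"))
    sub <- stats::setNames(sdf$subsystem, sdf$reaction_id)
  }
  flux_table(flux, subsystem = sub, fva_min = fmin, fva_max = fmax)
}

#' Write a flux table and its subsystem map to TSV
#' @param ft A [flux_table()].
#' @param path Flux matrix output path.
#' @param subsystem_path Optional subsystem map output path.
#' @export
write_flux <- function(ft, path, subsystem_path = NULL) {
  write_abundance(abundance_table(ft$flux), path, id_column = "reaction_id")
  if (!is.null(subsystem_path)) {
    utils::write.table(
      data.frame(reaction_id = rownames(ft$flux),
                 subsystem = ifelse(is.na(ft$subsystem), "", ft$subsystem),
                 stringsAsFactors = FALSE),
      subsystem_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
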