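## The DIRAC (Differential Rank Conservation) core. For a module of m
## analytes, each sample is reduced to a binary pair-order vector over the
## m(m-1)/2 ordered analyte pairs; a sample group's majority vote over these
## vectors is its rank consensus template; the rank matching score (RMS) of
## a sample against a template is the fraction of agreeing pairs; and the
## rank conservation index (RCI) of a group is the mean RMS of its samples
## under the group's own consensus. High RCI = tightly conserved ordering,
## low RCI = unpatterned behavior.
##
## Conventions (fixed, configurable knobs noted):
##  - pairs (i, j) are enumerated with i < j in sorted analyte-id order
##    (byte-order sort for determinism; any fixed order is equivalent);
##  - sample bit = 1 iff value_i > value_j (strict; ties give 0);
##  - majority tie at even group size resolves to 1.
## These tie rules keep the own-consensus bound RCI >= 1/2 exact: per pair
## the template matches max(k, n-k) >= n/2 of the n group samples.

# Deterministic analyte order: byte-wise (C-locale) radix sort.
sorted_ids <- function(ids) sort(ids, method = "radix")

# Pair index table for m analytes: all (i, j), i < j, in lexicographic
# order of the sorted ids. Returns list(i, j) of equal-length indices.
pair_index <- function(m) {
  if (m < 2L) fail("a module needs >= 2 analytes to form pairs")
  i <- rep(seq_len(m - 1L), times = (m - 1L):1L)
  j <- unlist(lapply(seq_len(m - 1L), function(k) seq.int(k + 1L, m)),
              use.names = FALSE)
  list(i = i, j = j)
}

#' Pair-order vector of one sample over one module
#'
#' Encodes a sample's within-module ordering as a binary vector over all
#' analyte pairs (i, j), i < j in sorted analyte-id order: the bit is 1 iff
#' the value of analyte i strictly exceeds the value of analyte j (ties
#' give 0).
#'
#' @param values Named numeric vector: the sample's abundance values for the
#'   module's analytes. Must be complete (no `NA`).
#' @return List with `analytes` (the sorted ids) and `bits` (integer 0/1
#'   vector of length m(m-1)/2, named `"i>j"`).
#' @examples
#' pair_order_vector(c(A = 0.5, B = 1.2, C = -0.3))$bits  # (0, 1, 1)
#' @export
pair_order_vector <- function(values) {
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    fail("values must be named by analyte id")
  }
  if (length(values) < 2L) fail("a module needs >= 2 analytes")
  if (anyNA(values)) fail("pair_order_vector requires complete values")
  ids <- sorted_ids(names(values))
  v <- values[ids]
  p <- pair_index(length(ids))
  bits <- as.integer(v[p$i] > v[p$j])
  names(bits) <- paste0(ids[p$i], ">", ids[p$j])
  list(analytes = ids, bits = bits)
}

# Coerce rank_consensus()/rank_matching_score() inputs to a bits matrix
# (pairs x samples).
as_bits_matrix <- function(vectors) {
  if (is.list(vectors) && !is.null(vectors$bits)) vectors <- list(vectors)
  if (is.list(vectors)) {
    lens <- vapply(vectors, function(v) length(v$bits), integer(1))
    if (length(unique(lens)) > 1L) {
      fail("pair-order vectors have inconsistent lengths: %s",
           paste(unique(lens), collapse = ", "))
    }
    vectors <- vapply(vectors, function(v) as.integer(v$bits),
                      integer(lens[1L]))
    vectors <- matrix(vectors, nrow = lens[1L])
  }
  storage.mode(vectors) <- "integer"
  vectors
}

#' Majority-vote rank consensus of a sample group
#'
#' Per analyte pair, the template bit is the majority bit over the group's
#' pair-order vectors; an exact tie (possible at even group size) resolves
#' to 1. `support` records, per pair, the fraction of samples agreeing with
#' the template bit, which the tie-break keeps in [1/2, 1].
#'
#' @param vectors Either a list of [pair_order_vector()] results or an
#'   integer 0/1 matrix (pairs x samples) with >= 2 columns.
#' @return List with `bits` (integer template) and `support` (numeric).
#' @export
rank_consensus <- function(vectors) {
  bm <- as_bits_matrix(vectors)
  n <- ncol(bm)
  if (n < 2L) fail("rank consensus needs >= 2 samples, got %d", n)
  ones <- rowSums(bm)
  bits <- as.integer(2L * ones >= n)
  support <- pmax(ones, n - ones) / n
  list(bits = bits, support = support, n_samples = n)
}

#' Rank matching score of a sample against a consensus template
#'
#' The fraction of analyte pairs on which the sample's pair-order vector
#' agrees with the template; always in [0, 1].
#'
#' @param v A [pair_order_vector()] result or integer 0/1 vector.
#' @param template A [rank_consensus()] result or integer 0/1 vector.
#' @return Scalar in [0, 1].
#' @export
rank_matching_score <- function(v, template) {
  vb <- if (is.list(v)) v$bits else v
  tb <- if (is.list(template)) template$bits else template
  if (length(vb) != length(tb)) {
    fail("pair-order vector (%d) and template (%d) lengths differ",
         length(vb), length(tb))
  }
  mean(vb == tb)
}

#' Rank conservation index of a group
#'
#' The arithmetic mean of the group's rank matching scores under its own
#' majority-vote consensus. Under the package's tie rules the own-consensus
#' RCI is bounded below by 1/2.
#'
#' @param vectors Pair-order vectors of the group's samples (list or
#'   pairs x samples 0/1 matrix).
#' @return Scalar RCI in [1/2, 1].
#' @export
rci <- function(vectors) {
  bm <- as_bits_matrix(vectors)
  if (ncol(bm) == 0L) fail("rci of an empty group is undefined")
  tmpl <- rank_consensus(bm)
  mean(colMeans(bm == tmpl$bits))
}

#' Rank matching scores and conservation indices for a study
#'
#' The main DIRAC computation. For every module, every scored sample
#' receives a rank matching score against the majority-vote consensus of
#' every requested consensus group; the RCI table summarizes own-consensus
#' scores (group mean of its own samples' RMS under its own template).
#' Consensus templates are always built from all of a group's samples
#' present in the table, so foreign cohorts can be scored against them
#' (cross-dataset scoring): scored samples need not belong to any consensus
#' group, and RCI rows exist only for consensus groups with scored samples
#' of their own.
#'
#' @param table Complete-case, preprocessed [abundance_table()].
#' @param meta [sample_metadata()] covering the table's samples.
#' @param modules A [module_set()] whose members are all measured (build it
#'   with [build_filtered_modules()]).
#' @param consensus_groups Groups whose templates to build; default all
#'   groups in `meta` present in the table. Each needs >= 2 samples.
#' @param scored_samples Samples to score; default all table samples.
#' @return Object of class `dirac_result`: list with
#'   \describe{
#'     \item{rms}{long data.frame (sample_id, group, module_id,
#'       consensus_group, rms)}
#'     \item{rci}{data.frame (group, module_id, rci, n_samples)}
#'     \item{templates}{per module, per consensus group: bits and support}
#'   }
#' @export
dirac_rms <- function(table, meta, modules, consensus_groups = NULL,
                      scored_samples = NULL) {
  meta <- match_metadata(table, meta)
  v <- ab_values(table)
  if (!length(modules$members)) fail("module set is empty")
  groups_present <- unique(meta$group)
  if (is.null(consensus_groups)) consensus_groups <- groups_present
  absent <- setdiff(consensus_groups, groups_present)
  if (length(absent)) {
    fail("consensus group(s) not in metadata: %s", paste(absent, collapse = ", "))
  }
  if (is.null(scored_samples)) scored_samples <- colnames(v)
  bad <- setdiff(scored_samples, colnames(v))
  if (length(bad)) {
    fail("scored sample(s) not in table: %s", paste(bad, collapse = ", "))
  }
  group_cols <- lapply(consensus_groups, function(g) {
    which(meta$group == g)
  })
  names(group_cols) <- consensus_groups
  small <- consensus_groups[vapply(group_cols, length, integer(1)) < 2L]
  if (length(small)) {
    fail("consensus group(s) with < 2 samples: %s", paste(small, collapse = ", "))
  }
  sample_group <- stats::setNames(meta$group, meta$sample_id)
  scored_idx <- match(scored_samples, colnames(v))

  rms_parts <- vector("list", length(modules$members))
  rci_parts <- vector("list", length(modules$members))
  templates <- vector("list", length(modules$members))
  names(templates) <- names(modules$members)

  for (mi in seq_along(modules$members)) {
    mid <- names(modules$members)[mi]
    members <- sorted_ids(modules$members[[mid]])
    missing <- setdiff(members, rownames(v))
    if (length(missing)) {
      fail("module %s has unmeasured member(s): %s", mid,
           paste(missing, collapse = ", "))
    }
    m <- length(members)
    if (m < 2L) fail("module %s has < 2 measured members", mid)
    sub <- v[members, , drop = FALSE]
    if (anyNA(sub)) fail("module %s has missing values; preprocess first", mid)
    p <- pair_index(m)
    bits <- (sub[p$i, , drop = FALSE] > sub[p$j, , drop = FALSE]) + 0L

    tmpl_list <- lapply(group_cols, function(cols) {
      rank_consensus(bits[, cols, drop = FALSE])
    })
    templates[[mid]] <- tmpl_list

    scored_bits <- bits[, scored_idx, drop = FALSE]
    rms_mat <- vapply(tmpl_list, function(t) {
      colMeans(scored_bits == t$bits)
    }, numeric(length(scored_idx)))
    rms_mat <- matrix(rms_mat, nrow = length(scored_idx),
                      dimnames = list(scored_samples, consensus_groups))

    rms_parts[[mi]] <- data.frame(
      sample_id = rep(scored_samples, times = length(consensus_groups)),
      group = rep(unname(sample_group[scored_samples]),
                  times = length(consensus_groups)),
      module_id = mid,
      consensus_group = rep(consensus_groups, each = length(scored_samples)),
      rms = as.vector(rms_mat),
      stringsAsFactors = FALSE)

    own <- lapply(consensus_groups, function(g) {
      own_samples <- intersect(scored_samples,
                               meta$sample_id[meta$group == g])
      if (!length(own_samples)) return(NULL)
      data.frame(group = g, module_id = mid,
                 rci = mean(rms_mat[own_samples, g]),
                 n_samples = length(own_samples),
                 stringsAsFactors = FALSE)
    })
    rci_parts[[mi]] <- do.call(rbind, own)
  }

  res <- list(rms = do.call(rbind, rms_parts),
              rci = do.call(rbind, rci_parts),
              templates = templates,
              consensus_groups = consensus_groups)
  rownames(res$rms) <- NULL
  rownames(res$rci) <- NULL
  class(res) <- "dirac_result"
  dlog("dirac_rms: %d modules, %d scored samples, %d consensus groups -> %d RMS rows",
       length(modules$members), length(scored_samples),
       length(consensus_groups), nrow(res$rms))
  res
}

#' @export
print.dirac_result <- function(x, ...) {
  cat(sprintf("dirac_result: %d RMS rows (%d modules x %d consensus groups), %d RCI rows\n",
              nrow(x$rms), length(x$templates), length(x$consensus_groups),
              nrow(x$rci)))
  invisible(x)
}
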