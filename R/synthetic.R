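## Synthetic data with known ground truth. The generator plants exactly the
## structure the rank-conservation analysis assumes: per module and group, a
## consensus ordering pi and a noise scale sigma; member means are
## delta-spaced along pi and samples add i.i.d. Gaussian noise, so the
## adjacent-pair inversion probability is pnorm(-delta / (sigma * sqrt(2)))
## and tightness is controlled purely by the delta/sigma ratio. Shared vs
## group-specific orderings make "similarly" vs "dissimilarly" changed
## unambiguous in truth; additive per-analyte sex/age effects exercise the
## covariate regression; ghost (annotated-but-unmeasured) members and
## coverage decoys exercise the module filter; flux tables with planted
## subsystem shifts and pseudo-reaction decoys exercise the flux stage.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards: randomness never leaks between calls or into the session.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Number of discordant pairs (Kendall distance) between two orderings given
# as member vectors (first = highest mean).
kendall_distance <- function(a, b) {
  pos <- match(a, b)
  p <- pair_index(length(a))
  sum(pos[p$i] > pos[p$j])
}

# Draw a random permutation of `members` whose Kendall distance to every
# reference ordering lies in [floor_frac, cap_frac] of all pairs, so
# group-specific orderings are unambiguously distinct from the shared one
# and from each other. The cap matters for feasibility: distances to a
# permutation and to its reverse sum to the pair count, so two references
# near reversal would leave no room for a third mutually distant ordering.
# Returns NULL when no candidate is found (caller restarts the whole set).
distant_permutation <- function(members, references, floor_frac = 0.55,
                                cap_frac = 0.75, tries = 2000L) {
  if (!is.list(references)) references <- list(references)
  npairs <- choose(length(members), 2)
  for (k in seq_len(tries)) {
    cand <- sample(members)
    d <- vapply(references, kendall_distance, numeric(1), a = cand)
    if (all(d >= floor_frac * npairs & d <= cap_frac * npairs)) return(cand)
  }
  NULL
}

# Draw the full set of orderings for one module: the first ordering is
# free, later ones must sit in the Kendall band relative to all earlier
# ones. Restarts from scratch when the sampler corners itself.
draw_ordering_set <- function(members, ordering_ids) {
  for (restart in seq_len(100L)) {
    ord <- list()
    ok <- TRUE
    for (oid in ordering_ids) {
      cand <- if (!length(ord)) sample(members) else distant_permutation(members, ord)
      if (is.null(cand)) {
        ok <- FALSE
        break
      }
      ord[[oid]] <- cand
    }
    if (ok) return(ord)
  }
  fail("could not draw %d mutually distant orderings for a module of size %d",
       length(ordering_ids), length(members))
}

#' Specify one synthetic module
#'
#' @param module_id Module identifier.
#' @param size Number of measured members (>= 4, respecting the coverage
#'   filter's minimum).
#' @param delta Spacing of member means along the consensus ordering.
#' @param sigma Named numeric: per-group noise standard deviation.
#' @param consensus Named character: per-group ordering id; groups sharing
#'   an id share the same drawn ordering, distinct ids get independently
#'   drawn orderings separated by a Kendall-distance floor.
#' @param ghost Number of annotated-but-unmeasured members (inflates
#'   `background_size` to exercise the coverage filter).
#' @return A `module_spec` list.
#' @export
module_spec <- function(module_id, size, delta = 1, sigma, consensus,
                        ghost = 0L) {
  if (size < 4L) fail("module %s: size %d < 4 (coverage filter minimum)",
                      module_id, size)
  if (delta < 0 || any(sigma <= 0)) fail("module %s: need delta >= 0 and sigma > 0",
                                         module_id)
  if (is.null(names(sigma)) || is.null(names(consensus))) {
    fail("module %s: sigma and consensus must be named by group", module_id)
  }
  structure(list(module_id = module_id, size = as.integer(size),
                 delta = delta, sigma = sigma,
                 consensus = consensus, ghost = as.integer(ghost)),
            class = "module_spec")
}

# Balanced metadata: sexes and ages crossed within each group, cycling when
# n_per_group is not a multiple of the cell count.
balanced_metadata <- function(groups, n_per_group, sexes = c("F", "M"),
                              ages = c("6", "12")) {
  cells <- expand.grid(sex = sexes, age_months = ages,
                       stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(groups, function(g) {
    idx <- rep(seq_len(nrow(cells)), length.out = n_per_group)
    data.frame(sample_id = sprintf("%s_s%02d", gsub("[^A-Za-z0-9]", "", g),
                                   seq_len(n_per_group)),
               group = g, sex = cells$sex[idx],
               age_months = cells$age_months[idx],
               stringsAsFactors = FALSE)
  }))
  sample_metadata(rows)
}

#' Generate a synthetic abundance study
#'
#' Draws a full abundance dataset from the generator's model: for each
#' module and group, member means are `delta`-spaced along the group's
#' consensus ordering and samples add i.i.d. Gaussian noise of the group's
#' `sigma`; background analytes are i.i.d. standard normal; every analyte
#' receives additive sex and age effects with coefficients drawn from
#' `Normal(0, beta_sd^2)`. Fully reproducible from `seed`; the caller's RNG
#' state is untouched.
#'
#' @param groups Character vector of group labels.
#' @param n_per_group Samples per group.
#' @param modules List of [module_spec()]s.
#' @param n_background Number of unstructured background analytes.
#' @param beta_sd Standard deviation of the per-analyte sex/age
#'   coefficients (0 disables covariate effects).
#' @param sexes,ages Covariate levels crossed within each group.
#' @param seed Integer seed.
#' @return List: `abundance` ([abundance_table()]), `metadata`
#'   ([sample_metadata()]), `modules` (annotation [module_set()] including
#'   ghost members), `truth` (per-module orderings/sigma/delta, covariate
#'   coefficients).
#' @export
generate_abundance <- function(groups, n_per_group, modules,
                               n_background = 0L, beta_sd = 0,
                               sexes = c("F", "M"), ages = c("6", "12"),
                               seed = 1L) {
  if (!length(modules)) fail("need >= 1 module spec")
  for (sp in modules) {
    missing <- setdiff(groups, names(sp$sigma))
    if (length(missing)) {
      fail("module %s: sigma missing for group(s) %s", sp$module_id,
           paste(missing, collapse = ", "))
    }
    if (length(setdiff(groups, names(sp$consensus)))) {
      fail("module %s: consensus missing for some group(s)", sp$module_id)
    }
  }
  meta <- balanced_metadata(groups, n_per_group, sexes, ages)
  n_samples <- nrow(meta)
  with_seed(seed, {
    member_ids <- lapply(modules, function(sp) {
      sprintf("%s_m%02d", sp$module_id, seq_len(sp$size))
    })
    names(member_ids) <- vapply(modules, `[[`, character(1), "module_id")
    ghost_ids <- lapply(modules, function(sp) {
      if (sp$ghost > 0L) sprintf("%s_g%02d", sp$module_id, seq_len(sp$ghost))
      else character(0)
    })
    names(ghost_ids) <- names(member_ids)

    # one drawn ordering per (module, ordering id); the first id drawn is
    # the reference for the Kendall-distance floor of later ones
    orderings <- lapply(modules, function(sp) {
      ids <- unique(unname(sp$consensus[groups]))
      mem <- sprintf("%s_m%02d", sp$module_id, seq_len(sp$size))
      draw_ordering_set(mem, ids)
    })
    names(orderings) <- names(member_ids)

    analyte_ids <- c(unlist(member_ids, use.names = FALSE),
                     if (n_background > 0L) sprintf("BG_%04d", seq_len(n_background)))
    values <- matrix(NA_real_, length(analyte_ids), n_samples,
                     dimnames = list(analyte_ids, meta$sample_id))

    for (sp in modules) {
      mem <- member_ids[[sp$module_id]]
      for (g in groups) {
        ord <- orderings[[sp$module_id]][[sp$consensus[[g]]]]
        # first member of the ordering gets the highest mean
        mu <- stats::setNames(sp$delta * rev(seq_along(ord)), ord)[mem]
        cols <- meta$sample_id[meta$group == g]
        values[mem, cols] <- mu +
          matrix(stats::rnorm(length(mem) * length(cols), 0, sp$sigma[[g]]),
                 length(mem), length(cols))
      }
    }
    if (n_background > 0L) {
      bg <- sprintf("BG_%04d", seq_len(n_background))
      values[bg, ] <- matrix(stats::rnorm(n_background * n_samples),
                             n_background, n_samples)
    }

    beta_sex <- stats::setNames(stats::rnorm(length(analyte_ids), 0, beta_sd),
                                analyte_ids)
    beta_age <- stats::setNames(stats::rnorm(length(analyte_ids), 0, beta_sd),
                                analyte_ids)
    if (beta_sd > 0) {
      is_male <- as.numeric(meta$sex == sexes[length(sexes)])
      is_old <- as.numeric(meta$age_months == ages[length(ages)])
      values <- values + outer(beta_sex, is_male) + outer(beta_age, is_old)
    }

    annotation <- module_set(
      stats::setNames(lapply(names(member_ids), function(mid) {
        c(member_ids[[mid]], ghost_ids[[mid]])
      }), names(member_ids)))

    truth <- list(
      modules = stats::setNames(lapply(modules, function(sp) {
        list(members = member_ids[[sp$module_id]],
             orderings = orderings[[sp$module_id]],
             consensus = sp$consensus, sigma = sp$sigma, delta = sp$delta,
             ghost = ghost_ids[[sp$module_id]])
      }), names(member_ids)),
      beta_sex = beta_sex, beta_age = beta_age, seed = seed)

    list(abundance = abundance_table(values), metadata = meta,
         modules = annotation, truth = truth)
  })
}

#' Generate a synthetic flux study
#'
#' Baseline flux per reaction is `Normal(mu_r, 1)` with reaction-level
#' means `mu_r ~ Normal(0, 2)`; planted reactions add a shift `delta` in the
#' designated groups. Decoy reactions without subsystem annotation and in
#' the excluded pseudo-reaction subsystems are included to exercise
#' [filter_functional_reactions()].
#'
#' @param groups Group labels.
#' @param n_per_group Samples per group.
#' @param subsystems Named integer: functional subsystem sizes (reaction
#'   counts).
#' @param shifts List of `list(subsystem =, n =, delta =, groups =)`:
#'   plant `n` shifted reactions of size `delta` in `subsystem` for the
#'   given groups.
#' @param n_unannotated,n_excluded Decoy counts (excluded decoys are spread
#'   over transport / exchange-demand / miscellaneous labels).
#' @param seed Integer seed.
#' @return List: `flux` ([flux_table()]), `metadata`, `truth` (per-reaction
#'   shifted groups and effect sizes).
#' @export
generate_flux <- function(groups, n_per_group, subsystems,
                          shifts = list(), n_unannotated = 4L,
                          n_excluded = 6L, seed = 1L) {
  meta <- balanced_metadata(groups, n_per_group)
  with_seed(seed + 1L, {
    rx <- unlist(lapply(names(subsystems), function(s) {
      stats::setNames(
        rep(s, subsystems[[s]]),
        sprintf("%s_r%03d", gsub("[^A-Za-z0-9]", "", s),
                seq_len(subsystems[[s]])))
    }))
    decoy_labels <- rep(c("Transport reactions", "Exchange/demand reactions",
                          "Miscellaneous"), length.out = n_excluded)
    decoys <- c(stats::setNames(rep(NA_character_, n_unannotated),
                                if (n_unannotated > 0L) sprintf("UNANN_r%03d", seq_len(n_unannotated)) else character(0)),
                stats::setNames(decoy_labels,
                                if (n_excluded > 0L) sprintf("DECOY_r%03d", seq_len(n_excluded)) else character(0)))
    subsystem <- c(rx, decoys)
    reaction_ids <- names(subsystem)
    mu <- stats::rnorm(length(reaction_ids), 0, 2)
    flux <- matrix(stats::rnorm(length(reaction_ids) * nrow(meta)),
                   length(reaction_ids), nrow(meta),
                   dimnames = list(reaction_ids, meta$sample_id)) + mu

    shifted <- list()
    for (sh in shifts) {
      pool <- names(rx)[rx == sh$subsystem]
      if (length(pool) < sh$n) {
        fail("subsystem '%s' has %d reactions; cannot plant %d shifts",
             sh$subsystem, length(pool), sh$n)
      }
      picked <- pool[seq_len(sh$n)]  # deterministic: first n of the subsystem
      for (r in picked) {
        cols <- meta$sample_id[meta$group %in% sh$groups]
        flux[r, cols] <- flux[r, cols] + sh$delta
        shifted[[r]] <- list(groups = sh$groups, delta = sh$delta,
                             subsystem = sh$subsystem)
      }
    }
    list(flux = flux_table(flux, subsystem = subsystem), metadata = meta,
         truth = list(shifted = shifted,
                      decoy_ids = names(decoys), seed = seed))
  })
}

#' One-call synthetic intervention study
#'
#' The package's reference scenario: four groups (Control plus three
#' interventions) of 12 samples each (sex- and age-balanced), modules of
#' eight members with unit mean spacing, and a planted truth covering every
#' label the analysis can produce:
#' \itemize{
#'   \item modules tightened by all three interventions on a consensus
#'     ordering *shared* with control (the "tightened by all, similar"
#'     ground truth);
#'   \item modules tightened by all three but each on its *own* distinct
#'     ordering (tightened, dissimilar);
#'   \item modules tightened by only two interventions;
#'   \item null modules (all groups loose, shared ordering);
#'   \item coverage-decoy modules that must fall to the module filter;
#'   \item a flux table with shifts concentrated in one subsystem for one
#'     intervention, a smaller planted subsystem for another, none for the
#'     third, plus pseudo-reaction decoys.
#' }
#' Noise scales default to `sigma_loose = 2.5` (loose; adjacent-pair
#' inversion probability ~0.39) and `sigma_tight = 0.35` (tight; ~0.02).
#' With `null = TRUE` all modules are generated loose with a shared
#' ordering and no flux shifts are planted (global-null variant).
#'
#' @param seed Integer seed.
#' @param n_tight_all_shared,n_tight_all_distinct,n_tight_two,n_null
#'   Module counts per planted class.
#' @param module_size,delta,sigma_tight,sigma_loose,beta_sd,n_background
#'   Generator parameters (see [generate_abundance()]).
#' @param null Generate the no-effect variant.
#' @return List: `abundance`, `metadata`, `modules` (annotation including
#'   ghosts and filter decoys), `truth` (with `tightened_all_similar` etc.),
#'   `flux`, `flux_truth`, `groups`, `control`, `interventions`.
#' @export
simulate_intervention_study <- function(seed = 1L,
                                        n_tight_all_shared = 6L,
                                        n_tight_all_distinct = 4L,
                                        n_tight_two = 6L,
                                        n_null = 24L,
                                        module_size = 8L,
                                        delta = 1,
                                        sigma_tight = 0.35,
                                        sigma_loose = 2.5,
                                        beta_sd = 0.3,
                                        n_background = 160L,
                                        null = FALSE) {
  control <- "Control"
  interventions <- c("ACA", "17aE2", "Rapa")
  groups <- c(control, interventions)
  loose <- stats::setNames(rep(sigma_loose, 4L), groups)
  shared <- stats::setNames(rep("O1", 4L), groups)

  mk <- function(prefix, n, sigma, consensus, ghost) {
    lapply(seq_len(n), function(k) {
      module_spec(sprintf("%s%02d", prefix, k), size = module_size,
                  delta = delta, sigma = sigma, consensus = consensus,
                  ghost = ghost)
    })
  }
  if (null) {
    specs <- mk("NULLM", n_tight_all_shared + n_tight_all_distinct +
                  n_tight_two + n_null, loose, shared, ghost = 0L)
    classes <- list(tight_all_shared = character(0),
                    tight_all_distinct = character(0),
                    tight_two = character(0),
                    null = vapply(specs, `[[`, character(1), "module_id"))
  } else {
    tight3 <- loose
    tight3[interventions] <- sigma_tight
    tight2 <- loose
    tight2[c("ACA", "17aE2")] <- sigma_tight
    distinct <- stats::setNames(c("O1", "O_ACA", "O_17aE2", "O_Rapa"), groups)
    specs <- c(mk("TAS", n_tight_all_shared, tight3, shared, ghost = 2L),
               mk("TAD", n_tight_all_distinct, tight3, distinct, ghost = 0L),
               mk("TT", n_tight_two, tight2, shared, ghost = 1L),
               mk("NULLM", n_null, loose, shared, ghost = 0L))
    classes <- list(
      tight_all_shared = sprintf("TAS%02d", seq_len(n_tight_all_shared)),
      tight_all_distinct = sprintf("TAD%02d", seq_len(n_tight_all_distinct)),
      tight_two = sprintf("TT%02d", seq_len(n_tight_two)),
      null = sprintf("NULLM%02d", seq_len(n_null)))
  }
  # coverage decoys: too many unmeasured members -> filter must drop them
  decoys <- c(mk("LOWCOV", 2L, loose, shared, ghost = module_size + 2L),
              mk("SPARSE", 1L, loose, shared, ghost = 2L * module_size))

  ab <- generate_abundance(groups, n_per_group = 12L,
                           modules = c(specs, decoys),
                           n_background = n_background, beta_sd = beta_sd,
                           seed = seed)
  ab$truth$classes <- classes
  ab$truth$filter_decoys <- vapply(decoys, `[[`, character(1), "module_id")
  ab$truth$tightened_all_similar <- classes$tight_all_shared
  ab$truth$tightened_by <- list(
    ACA = c(classes$tight_all_shared, classes$tight_all_distinct,
            classes$tight_two),
    `17aE2` = c(classes$tight_all_shared, classes$tight_all_distinct,
                classes$tight_two),
    Rapa = c(classes$tight_all_shared, classes$tight_all_distinct))

  fl <- generate_flux(
    groups, n_per_group = 12L,
    subsystems = stats::setNames(rep(12L, 8L), sprintf("Subsystem %02d", 1:8)),
    shifts = if (null) list() else list(
      list(subsystem = "Subsystem 01", n = 8L, delta = 3, groups = "ACA"),
      list(subsystem = "Subsystem 02", n = 4L, delta = 3, groups = "17aE2")),
    seed = seed)

  c(ab, list(flux = fl$flux, flux_metadata = fl$metadata,
             flux_truth = fl$truth, groups = groups, control = control,
             interventions = interventions))
}

#' Write a synthetic study to the pipeline's standard input files
#'
#' Serializes a [simulate_intervention_study()] result (abundance TSV,
#' metadata TSV, annotation GMT, flux TSV, subsystem map TSV) so the full
#' pipeline can be driven from files; re-reading reproduces the objects.
#'
#' @param study Result of [simulate_intervention_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(abundance = file.path(dir, "abundance.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             modules = file.path(dir, "modules.gmt"),
             flux = file.path(dir, "flux.tsv"),
             subsystems = file.path(dir, "subsystems.tsv"))
  write_abundance(study$abundance, paths[["abundance"]])
  write_metadata(study$metadata, paths[["metadata"]])
  write_gmt(study$modules, paths[["modules"]])
  if (!is.null(study$flux)) {
    write_flux(study$flux, paths[["flux"]], paths[["subsystems"]])
  } else {
    paths <- paths[1:3]
  }
  paths
}
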