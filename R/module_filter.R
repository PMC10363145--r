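## Coverage-based module filtering. An annotated module is only
## biologically interpretable in a dataset if enough of it was measured:
## a module is retained iff at least half of its annotated members (rounded
## up for odd sizes - "at least half" read inclusively), and no fewer than
## four, were quantified.

#' Intersect modules with the measured analytes and apply the coverage filter
#'
#' Each module's members are replaced by their intersection with the
#' measured analyte set; the module is retained iff
#' `|members measured| >= max(4, ceiling(background_size / 2))`,
#' where `background_size` is the annotated size before intersection.
#' The filter is monotone: adding measured analytes never removes a
#' previously retained module.
#'
#' @param annotation A non-empty [module_set()] (e.g., from [read_gmt()]).
#' @param measured Character vector of measured analyte ids (e.g.,
#'   `rownames` of a preprocessed abundance table).
#' @return List with `modules` (the retained, intersected [module_set()];
#'   may be empty, which is flagged) and `audit`: data.frame
#'   (module_id, background, n_measured, coverage, retained).
#' @export
build_filtered_modules <- function(annotation, measured) {
  if (!length(annotation$members)) fail("annotation module set is empty")
  measured <- unique(as.character(measured))
  ids <- names(annotation$members)
  inter <- lapply(annotation$members, intersect, y = measured)
  bg <- annotation$background_size[ids]
  n_meas <- lengths(inter)
  need <- pmax(4L, as.integer(ceiling(bg / 2)))
  retained <- n_meas >= need
  audit <- data.frame(module_id = ids,
                      background = as.integer(bg),
                      n_measured = as.integer(n_meas),
                      coverage = as.numeric(n_meas) / as.numeric(bg),
                      retained = retained,
                      stringsAsFactors = FALSE)
  rownames(audit) <- NULL
  keep <- ids[retained]
  dlog("build_filtered_modules: %d of %d modules retained (>= max(4, ceil(background/2)) measured)",
       length(keep), length(ids))
  if (!length(keep)) dlog("build_filtered_modules: no module survives the coverage filter")
  mods <- module_set(inter[keep],
                     description = annotation$description[keep],
                     background_size = bg[keep])
  list(modules = mods, audit = audit)
}

#' Restrict two filtered module sets to their shared modules
#'
#' For comparisons across datasets or omic layers, both sets are restricted
#' to the intersection of module ids; each side keeps its own measured
#' member sets.
#'
#' @param a,b Filtered [module_set()]s (the `modules` element of
#'   [build_filtered_modules()]).
#' @return List of the two restricted module sets (`a`, `b`).
#' @export
restrict_to_shared_modules <- function(a, b) {
  shared <- intersect(names(a$members), names(b$members))
  if (!length(shared)) fail("module sets share no module ids")
  take <- function(ms) {
    module_set(ms$members[shared],
               description = ms$description[shared],
               background_size = ms$background_size[shared])
  }
  dlog("restrict_to_shared_modules: %d shared modules (from %d and %d)",
       length(shared), length(a$members), length(b$members))
  list(a = take(a), b = take(b))
}
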