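## Module sets in GMT form. A module is a named set of analyte identifiers;
## `background_size` records how many members the module had before being
## intersected with the measured analytes, which the coverage filter needs.

#' Construct a module set
#'
#' @param members Named list; each element a character vector of analyte
#'   identifiers (deduplicated, order not meaningful).
#' @param description Optional named character vector of free-text module
#'   descriptions (defaults to the module ids).
#' @param background_size Optional named integer vector: annotated module
#'   size before intersection with the measured analytes. Defaults to the
#'   member counts.
#' @return An object of class `module_set`: a list with elements `members`,
#'   `description`, `background_size`.
#' @export
module_set <- function(members, description = NULL, background_size = NULL) {
  if (!is.list(members)) fail("members must be a named list of character vectors")
  ids <- names(members)
  if (length(members) && (is.null(ids) || any(!nzchar(ids)))) {
    fail("every module needs a non-empty id")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) fail("duplicate module ids: %s", paste(dup, collapse = ", "))
  members <- lapply(members, function(m) unique(as.character(m)))
  if (any(lengths(members) == 0L)) {
    fail("empty member sets: %s",
         paste(ids[lengths(members) == 0L], collapse = ", "))
  }
  if (is.null(description)) description <- stats::setNames(ids, ids)
  if (is.null(background_size)) {
    background_size <- stats::setNames(lengths(members), ids)
  }
  background_size <- stats::setNames(as.integer(background_size[ids]), ids)
  if (anyNA(background_size) || any(background_size < lengths(members))) {
    fail("background_size must be defined for every module and >= member count")
  }
  structure(list(members = members,
                 description = stats::setNames(as.character(description[ids]), ids),
                 background_size = background_size),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d modules, member counts %s\n", length(x$members),
              if (length(x$members)) {
                paste0("[", min(lengths(x$members)), ", ",
                       max(lengths(x$members)), "]")
              } else "[]"))
  invisible(x)
}

#' @export
length.module_set <- function(x) length(x$members)

#' Read module definitions from a GMT file
#'
#' Standard GMT dialect: one module per line,
#' `module_id <tab> description <tab> member1 <tab> member2 ...`.
#' Duplicate members within a line are deduplicated with a warning. The
#' `background_size` of each module is initialized to its (deduplicated)
#' member count in the file.
#'
#' @param path GMT file path.
#' @return A [module_set()]. An empty file yields an empty set (later
#'   pipeline stages refuse it).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    dlog("read_gmt: %s is empty", path)
    return(module_set(stats::setNames(list(), character(0))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    fail("GMT line %d has %d field(s); need id, description and >=1 member",
         which(nf < 3L)[1L], nf[which(nf < 3L)[1L]])
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(members, function(m) sum(duplicated(m)), integer(1)))
  if (ndup > 0L) {
    warn("read_gmt: removed %d duplicated member entr%s within modules",
         ndup, if (ndup == 1L) "y" else "ies")
  }
  ms <- module_set(stats::setNames(members, ids),
                   description = stats::setNames(desc, ids))
  dlog("read_gmt: %d modules from %s", length(ms), path)
  ms
}

#' Write a module set to a GMT file
#' @param modules A [module_set()].
#' @param path Output path.
#' @export
write_gmt <- function(modules, path) {
  lines <- vapply(names(modules$members), function(id) {
    paste(c(id, modules$description[[id]], modules$members[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
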