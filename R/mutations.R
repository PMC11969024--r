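#' Parse point-mutation labels
#'
#' Mutations are written in the conventional `"Y5W"` form: parental residue,
#' 1-based position, replacement residue (e.g. `T6D`, `A7D`).
#'
#' @param x Character vector of mutation labels.
#' @return A tibble with columns `mutation`, `position`, `from_aa`, `to_aa`.
#' @examples
#' parse_mutations(c("Y5W", "T6D"))
#' @export
parse_mutations <- function(x) {
  stopifnot(is.character(x))
  m <- regmatches(x, regexec("^([A-Z])([0-9]+)([A-Z])$", x))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    abort(paste0("malformed mutation label(s): ",
                 paste(x[bad], collapse = ", ")))
  }
  tibble(
    mutation = x,
    position = as.integer(vapply(m, `[`, character(1), 3L)),
    from_aa  = vapply(m, `[`, character(1), 2L),
    to_aa    = vapply(m, `[`, character(1), 4L)
  )
}

#' Apply a set of point mutations to a parent peptide
#'
#' Validates that each mutation's parental residue matches the parent sequence
#' at its position and that no two mutations target the same position, then
#' returns the substituted sequence.
#'
#' @param parent Parent peptide as a single amino-acid string.
#' @param mutations Character vector of labels such as `"Y5W"`, or a data frame
#'   as returned by [parse_mutations()]. An empty vector returns the parent.
#' @return The mutated peptide (single string, same length as `parent`).
#' @examples
#' apply_mutations("EEDDYTTAAPLTCFTT", c("Y5W", "T6D"))
#' @export
apply_mutations <- function(parent, mutations = character()) {
  stopifnot(is.character(parent), length(parent) == 1L, nchar(parent) >= 1L)
  muts <- if (is.data.frame(mutations)) mutations else parse_mutations(mutations)
  if (nrow(muts) == 0L) return(parent)
  if (anyDuplicated(muts$position)) {
    dup <- unique(muts$position[duplicated(muts$position)])
    abort(paste0("conflicting mutations at position(s): ",
                 paste(dup, collapse = ", ")))
  }
  if (any(muts$position < 1L | muts$position > nchar(parent))) {
    abort("mutation position outside parent sequence")
  }
  aa <- strsplit(parent, "")[[1]]
  mismatch <- aa[muts$position] != muts$from_aa
  if (any(mismatch)) {
    abort(paste0("parental residue mismatch for: ",
                 paste(muts$mutation[mismatch], collapse = ", ")))
  }
  if (any(muts$from_aa == muts$to_aa)) {
    abort("mutation replaces a residue with itself")
  }
  aa[muts$position] <- muts$to_aa
  paste(aa, collapse = "")
}

#' Express a variant as mutations relative to a parent
#'
#' @param peptide,parent Equal-length amino-acid strings.
#' @return Tibble of mutations (zero rows for the parent itself).
#' @export
mutations_from_parent <- function(peptide, parent) {
  stopifnot(nchar(peptide) == nchar(parent))
  a <- strsplit(parent, "")[[1]]
  b <- strsplit(peptide, "")[[1]]
  idx <- which(a != b)
  tibble(
    mutation = paste0(a[idx], idx, b[idx]),
    position = as.integer(idx),
    from_aa  = a[idx],
    to_aa    = b[idx]
  )
}

format_mutations <- function(muts) {
  if (nrow(muts) == 0L) return("")
  muts <- dplyr::arrange(muts, .data$position)
  paste(muts$mutation, collapse = "+")
}
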