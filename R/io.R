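## File formats.  GP maps travel as two-column TSV (genotype <TAB>
## phenotype label, '#' comments, optional "genotype phenotype" header);
## phenotype partitions as two-column TSV (phenotype <TAB> group).  All
## tabular results are written as plain CSV with '.' decimal separator.

#' Read a complete GP map from a two-column table
#'
#' Parses a text table with one genotype string and one phenotype label per
#' line (tab- or whitespace-separated; lines starting with `#` are
#' comments; an optional `genotype<TAB>phenotype` header row is skipped).
#' All genotypes must have the same length; the alphabet is inferred from
#' the observed symbols in sorted order unless `symbols` is given.  The map
#' must be total over the Hamming graph: genotypes absent from the file are
#' an error unless `defaultPhenotype` supplies a fill-in label (e.g. `"."`
#' for unfolded sequences).  Duplicate rows are accepted with a message
#' when consistent and rejected when conflicting.
#'
#' @param path file path.
#' @param symbols optional alphabet (character vector of single characters,
#'   digit order); inferred when `NULL`.
#' @param defaultPhenotype optional label assigned to genotypes missing
#'   from the file.
#' @return a [GPMap-class].
#' @seealso [writeGPMap()], [GPMap()]
#' @export
readGPMap <- function(path, symbols = NULL, defaultPhenotype = NULL) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = "character", col.names = c("g", "p"),
                           stringsAsFactors = FALSE)
  if (nrow(tab) && tolower(tab$g[1]) == "genotype" &&
      tolower(tab$p[1]) == "phenotype")
    tab <- tab[-1, , drop = FALSE]
  if (!nrow(tab)) stop("no genotype rows in ", path)
  lens <- unique(nchar(tab$g))
  if (length(lens) != 1L)
    stop("ragged genotype lengths in ", path, ": ",
         paste(lens, collapse = ", "))
  observed <- sort(unique(unlist(strsplit(tab$g, "", fixed = TRUE))))
  if (is.null(symbols)) {
    symbols <- observed
    if (length(symbols) < 2L)
      stop("fewer than two distinct symbols observed; supply 'symbols'")
  } else if (!all(observed %in% symbols)) {
    stop("genotypes use symbols outside the declared alphabet: ",
         paste(setdiff(observed, symbols), collapse = ", "))
  }
  space <- GenotypeSpace(length(symbols), lens, symbols)
  v <- genotypeToVertex(tab$g, space)
  dup <- duplicated(v)
  if (any(dup)) {
    conflict <- tapply(tab$p, v, function(p) length(unique(p)) > 1)
    if (any(conflict))
      stop("duplicate genotypes with conflicting phenotypes: ",
           paste(utils::head(vertexToGenotype(
             as.numeric(names(conflict))[conflict], space), 5),
             collapse = ", "))
    message(sum(dup), " duplicate consistent row(s) collapsed")
    tab <- tab[!dup, , drop = FALSE]
    v <- v[!dup]
  }
  assignment <- rep(NA_character_, nGenotypes(space))
  assignment[v + 1] <- tab$p
  if (anyNA(assignment)) {
    if (is.null(defaultPhenotype))
      stop(sum(is.na(assignment)), " genotype(s) missing and no ",
           "'defaultPhenotype' given; the map must be total")
    assignment[is.na(assignment)] <- defaultPhenotype
  }
  GPMap(space, assignment)
}

#' Write a GP map as a two-column TSV
#'
#' @param map a [GPMap-class].
#' @param path output file.
#' @param header write a `genotype<TAB>phenotype` header row.
#' @return `path`, invisibly.
#' @export
writeGPMap <- function(map, path, header = TRUE) {
  g <- vertexToGenotype(0:(nGenotypes(map@space) - 1), map@space)
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("genotype\tphenotype", con)
  writeLines(paste(g, map@assignment, sep = "\t"), con)
  invisible(path)
}

#' Read a phenotype partition (coarse-graining) table
#'
#' Two-column TSV mapping each phenotype label to its coarse-grained group
#' label; `#` comments and an optional `phenotype<TAB>group` header are
#' skipped.
#'
#' @param path file path.
#' @return named character vector (names = phenotype labels, values =
#'   group labels) suitable for [coarseGrain()].
#' @export
readPartition <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = "character",
                           col.names = c("phenotype", "group"),
                           stringsAsFactors = FALSE)
  if (nrow(tab) && tolower(tab$phenotype[1]) == "phenotype")
    tab <- tab[-1, , drop = FALSE]
  if (anyDuplicated(tab$phenotype))
    stop("phenotype(s) listed twice in partition: ",
         paste(unique(tab$phenotype[duplicated(tab$phenotype)]),
               collapse = ", "))
  stats::setNames(tab$group, tab$phenotype)
}

#' Write a transition matrix as a square CSV with label header row/column
#'
#' @param tm a [TransitionMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTransitionMatrix <- function(tm, path) {
  m <- as.data.frame(tm@phi)
  utils::write.csv(cbind(label = rownames(tm@phi), m), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
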