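# Table I/O. All outputs are TSV with '.' decimal separator and 'NA' for
# missing; '#'-prefixed header lines carry provenance (tool version, seed,
# config hash) so identical configurations yield byte-identical files.

.write_tsv <- function(df, path, header_lines = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_lines))
    writeLines(paste0("# ", header_lines), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a cohort dataset to TSV files
#'
#' Writes `<name>_phenotypes.tsv`, `<name>_abundance.tsv` (subject ids in
#' the first column, a `# scale=` header flag) and, if present,
#' `<name>_annotation.tsv` under `dir`.
#'
#' @param cohort A [cohort_dataset()].
#' @param dir Output directory (created if needed).
#' @param header_lines Optional extra `#` header lines.
#' @return Invisibly, the written paths.
#' @export
write_cohort <- function(cohort, dir, header_lines = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(dir, cohort$name)
  .write_tsv(cohort$phenotypes, paste0(pre, "_phenotypes.tsv"), header_lines)
  ab <- data.frame(subject_id = rownames(cohort$abundance),
                   cohort$abundance, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(ab, paste0(pre, "_abundance.tsv"),
             c(header_lines, paste0("scale=", attr(cohort$abundance, "scale"))))
  paths <- paste0(pre, c("_phenotypes.tsv", "_abundance.tsv"))
  if (!is.null(cohort$annotation)) {
    .write_tsv(cohort$annotation, paste0(pre, "_annotation.tsv"),
               header_lines)
    paths <- c(paths, paste0(pre, "_annotation.tsv"))
  }
  invisible(paths)
}

#' Read a cohort dataset from TSV files
#'
#' Counterpart of [write_cohort()]: joins the phenotype table and abundance
#' matrix on subject id, honoring the `# scale=` flag of the abundance file
#' (raw matrices are log-transformed on load).
#'
#' @param dir Directory holding the files.
#' @param name Cohort name (file prefix).
#' @param annotation Optional annotation data frame; if `NULL` and
#'   `<name>_annotation.tsv` exists it is read from there.
#' @return A [cohort_dataset()].
#' @export
read_cohort <- function(dir, name, annotation = NULL) {
  ph_path <- file.path(dir, paste0(name, "_phenotypes.tsv"))
  ab_path <- file.path(dir, paste0(name, "_abundance.tsv"))
  for (p in c(ph_path, ab_path))
    if (!file.exists(p)) stop("missing cohort file: ", p, call. = FALSE)
  ph <- .read_tsv(ph_path)
  head_lines <- grep("^#", readLines(ab_path, n = 10), value = TRUE)
  scale <- if (any(grepl("scale=raw", head_lines))) "raw" else "log"
  ab <- .read_tsv(ab_path)
  m <- as.matrix(ab[, -1, drop = FALSE])
  rownames(m) <- ab[[1]]
  an_path <- file.path(dir, paste0(name, "_annotation.tsv"))
  if (is.null(annotation) && file.exists(an_path))
    annotation <- .read_tsv(an_path)
  cohort_dataset(name, ph, m, annotation = annotation, scale = scale)
}

#' Read a GMT set-definition file
#'
#' Tab-separated lines: set name, description, then member ids. Duplicate
#' members within a set are deduplicated with a warning; a duplicated set
#' name or a line with fewer than two fields is a parse error reporting the
#' line number. Empty member lists are allowed (such sets are later
#' excluded by the minimum-size rule).
#'
#' @param path GMT file path.
#' @return Named list: set name -> character vector of members, with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list()
  desc <- character(0)
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    if (length(f) < 2)
      stop("malformed GMT line ", i, ": expected name<TAB>description",
           call. = FALSE)
    nm <- f[1]
    if (nm %in% names(sets))
      stop("duplicated set name '", nm, "' at GMT line ", i, call. = FALSE)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", nm, "' deduplicated")
      members <- unique(members)
    }
    sets[[nm]] <- members
    desc[nm] <- f[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write metabolite sets as GMT
#'
#' @param sets Named list: set name -> member ids.
#' @param path Output path.
#' @param descriptions Optional named descriptions; defaults to the set
#'   names.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
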