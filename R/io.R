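#' Read a feature-by-sample omics matrix from TSV
#'
#' Expects a tab-separated file whose first column holds the feature key and
#' whose remaining columns are samples (header row with sample ids). Missing
#' cells are written `NA` or left empty; any other non-numeric cell is a
#' parse error. Duplicate feature keys and ragged rows are rejected with the
#' offending line number.
#'
#' @param path Path to the TSV file.
#' @param level Omic level tag (see [OmicsMatrix-class]).
#' @return An [OmicsMatrix-class]; sample and row order follow the file.
#' @export
readOmicsMatrix <- function(path, level) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("matrix file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  ncols <- length(header)
  if (ncols < 2L) stop("line 1: header needs a key column and >=1 sample")
  samples <- header[-1L]
  nr <- length(lines) - 1L
  keys <- character(nr)
  vals <- matrix(NA_real_, nr, ncols - 1L)
  for (i in seq_len(nr)) {
    f <- fields[[i + 1L]]
    # trailing empty fields are dropped by strsplit; pad them back
    if (length(f) < ncols && !nzchar(sub("[^\t]*$", "x", lines[i + 1L])))
      f <- c(f, rep("", ncols - length(f)))
    if (length(f) != ncols)
      stop(sprintf("line %d: expected %d fields, found %d",
        i + 1L, ncols, length(f)))
    keys[i] <- f[1L]
    cells <- f[-1L]
    cells[cells == "" | cells == "NA"] <- NA
    v <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(v) & !is.na(cells))
    if (length(bad))
      stop(sprintf("line %d: non-numeric cell '%s' in column %d",
        i + 1L, cells[bad[1L]], bad[1L] + 1L))
    vals[i, ] <- v
  }
  dup <- which(duplicated(keys))
  if (length(dup))
    stop(sprintf("line %d: duplicate feature key '%s'",
      dup[1L] + 1L, keys[dup[1L]]))
  dimnames(vals) <- list(keys, samples)
  OmicsMatrix(vals, level)
}

#' Write an OmicsMatrix to TSV
#'
#' Inverse of [readOmicsMatrix()]: first column `feature`, then one column
#' per sample; missing cells written as `NA`.
#'
#' @param x An [OmicsMatrix-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeOmicsMatrix <- function(x, path) {
  v <- omicsValues(x)
  df <- data.frame(feature = rownames(v), v,
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated gene symbols.
#' Lines with no genes are an error (naming the line).
#'
#' @param path Path to the GMT file.
#' @return A [GeneSetCollection-class].
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("line %d: gene set '%s' has no member genes",
        i, if (length(f)) f[1L] else ""))
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop(sprintf("line %d: gene set '%s' has no member genes", i, f[1L]))
    if (f[1L] %in% names(sets))
      stop(sprintf("line %d: duplicate set name '%s'", i, f[1L]))
    sets[[f[1L]]] <- genes
    desc[f[1L]] <- f[2L]
  }
  GeneSetCollection(sets, desc)
}

#' Write gene sets to a GMT file
#'
#' @param gsc A [GeneSetCollection-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(gsc, path) {
  s <- geneSets(gsc)
  lines <- vapply(names(s), function(nm) {
    paste(c(nm, gsc@description[[nm]], s[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

.MUTATION_COLS <- c("sample", "gene", "protein_change", "vaf", "cohort")

#' Read a MAF-like somatic mutation table
#'
#' Tab-separated with header columns `sample`, `gene`, `protein_change`
#' (e.g. `p.H1047R`), `vaf` (fraction in \[0, 1\], may be `NA`) and
#' `cohort` (`tumour` or `pdx`).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of mutation records.
#' @export
readMutations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
    colClasses = c(vaf = "numeric"))
  miss <- setdiff(.MUTATION_COLS, names(df))
  if (length(miss))
    stop("mutation table lacks columns: ", paste(miss, collapse = ", "))
  validateMutations(df)
  df[.MUTATION_COLS]
}

#' @noRd
validateMutations <- function(df) {
  if (any(!nzchar(df$gene)) || any(!nzchar(df$protein_change)))
    stop("mutation records need non-empty gene and protein_change")
  bad <- !is.na(df$vaf) & (df$vaf < 0 | df$vaf > 1)
  if (any(bad))
    stop("vaf outside [0, 1] for ",
      paste(df$gene[bad][seq_len(min(3, sum(bad)))], collapse = ", "))
  invisible(df)
}

#' Write a mutation table to TSV
#'
#' @param df Mutation `data.frame` (see [readMutations()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMutations <- function(df, path) {
  utils::write.table(df[.MUTATION_COLS], path, sep = "\t",
    quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain gene list (one symbol per line)
#'
#' Used for druggable-gene lists; blank lines and `#` comments are skipped.
#'
#' @param path Path to the text file.
#' @return Character vector of unique gene symbols.
#' @export
readGeneList <- function(path) {
  g <- readLines(path)
  g <- trimws(g)
  unique(g[nzchar(g) & !startsWith(g, "#")])
}
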