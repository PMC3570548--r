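#' Read a tab-separated expression table
#'
#' Reads a TSV with a header row of sample identifiers and row identifiers
#' in the first column (or the transpose, with samples in rows).  Cells must
#' parse as decimal numbers; scientific notation is accepted, locale
#' separators are not.  Any non-numeric cell is an error naming its row and
#' column.
#'
#' @param path file path.
#' @param orientation `"rows"` if rows are probes/genes (the default),
#'   `"samples-in-rows"` for transposed input.
#' @param level `"PROBE"` or `"GENE"` (see [expression_matrix()]).
#' @param platform optional platform name recorded on the result.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, orientation = c("rows", "samples-in-rows"),
                                  level = c("GENE", "PROBE"), platform = "") {
  orientation <- match.arg(orientation)
  level <- match.arg(level)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("empty or header-only expression table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != widths[1L]))
    stop("ragged rows in ", path, " (line ",
         which(widths != widths[1L])[1L], ")")
  header <- fields[[1L]][-1L]
  body <- fields[-1L]
  ids <- vapply(body, `[[`, "", 1L)
  cells <- t(vapply(body, function(f) f[-1L], character(length(header))))
  if (length(header) == 1L) cells <- matrix(t(cells), ncol = 1L)
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                 cells[bad[1L], bad[2L]], ids[bad[1L]], header[bad[2L]], path))
  }
  dimnames(num) <- list(ids, header)
  if (orientation == "samples-in-rows") num <- t(num)
  expression_matrix(num, level = level, platform = platform)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_table()]; full precision (`%.17g`).
#'
#' @param x an [expression_matrix()] or numeric matrix with dimnames.
#' @param path output file.
#' @param id_header header for the identifier column.
#' @export
write_expression_table <- function(x, path, id_header = "ID") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_header, colnames(x)), collapse = "\t"), con)
  rows <- apply(x, 1L, function(v)
    paste(sprintf("%.17g", v), collapse = "\t"))
  writeLines(paste(rownames(x), rows, sep = "\t"), con)
  invisible(path)
}

#' Read a GMT signature collection
#'
#' Standard GMT: one signature per line, fields `name`, `source/description`,
#' then one gene per field.  Duplicate genes within a line are collapsed.
#'
#' @param path file path.
#' @return A list of signatures, each `list(name=, source=, genes=)`, in
#'   file order.  Empty file gives an empty list.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields in ", path)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    out[[i]] <- list(name = f[1L], source = f[2L], genes = genes)
  }
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Write a GMT signature collection
#'
#' @param signatures list of `list(name, source, genes)` entries, as
#'   returned by [read_gmt()] or [simulate_signature_db()].
#' @param path output file.
#' @export
write_gmt <- function(signatures, path) {
  lines <- vapply(signatures, function(s)
    paste(c(s$name, s$source %||% "na", s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column alias-to-approved symbol table
#'
#' TSV with columns `alias` and `approved`; an alias may occur on several
#' rows (one per candidate approved symbol).
#'
#' @param path file path.
#' @return Named list: alias -> character vector of approved symbols.
#' @export
read_symbol_table <- function(path) {
  tab <- read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(tab) < 2L) stop("symbol table needs two columns (alias, approved)")
  keep <- nzchar(tab[[2L]])
  split(tab[[2L]][keep], tab[[1L]][keep])
}

#' Re-annotate identifiers to approved gene symbols
#'
#' Each identifier is replaced by its approved symbol only when the mapping
#' is unambiguous (the alias maps to exactly one approved symbol); otherwise
#' the original identifier is kept verbatim.  Composite identifiers joined
#' with `#` (e.g. `"ISY1#RAB43"`) are treated as atomic and never remapped.
#' The operation is idempotent when the symbol table maps approved symbols
#' to themselves or leaves them absent.
#'
#' @param ids character vector of identifiers.
#' @param symbol_table named list as from [read_symbol_table()].
#' @return Character vector of the same length: the re-annotated ids.
#' @export
reannotate_symbols <- function(ids, symbol_table) {
  if (!length(ids)) stop("no identifiers supplied")
  out <- as.character(ids)
  for (i in seq_along(out)) {
    id <- out[[i]]
    if (grepl("#", id, fixed = TRUE)) next
    hit <- symbol_table[[id]]
    if (!is.null(hit)) {
      hit <- unique(hit[nzchar(hit)])
      if (length(hit) == 1L) out[[i]] <- hit
    }
  }
  out
}

quote_arff <- function(x) {
  need <- grepl("[ ,\t'\"{}%]", x) | !nzchar(x)
  x[need] <- paste0("'", gsub("'", "\\\\'", x[need]), "'")
  x
}

#' Write features and class labels as an ARFF file
#'
#' One numeric attribute per gene (columns of `features`), plus a nominal
#' `class` attribute with values `{ABC, GCB, TYPE_III}`.  Samples without a
#' label are written with the ARFF missing marker `?`.  Attribute names
#' containing spaces or other special characters are quoted per the ARFF
#' grammar, so the file round-trips through standard ARFF readers.
#'
#' @param features numeric matrix/data.frame, rows = samples, columns = genes.
#' @param labels character/factor of class labels aligned with rows, or
#'   `NULL`/`NA` entries for unlabeled samples.
#' @param relation_name ARFF \code{@relation} name.
#' @param path output file.
#' @export
write_arff <- function(features, labels = NULL, relation_name = "dac", path) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (is.null(labels)) labels <- rep(NA_character_, n)
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels do not align with samples")
  known <- labels[!is.na(labels)]
  if (length(known) && !all(known %in% DAC_CLASSES))
    stop("labels must be one of ", paste(DAC_CLASSES, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("@relation", quote_arff(relation_name)), con)
  for (g in colnames(features))
    writeLines(paste("@attribute", quote_arff(g), "numeric"), con)
  writeLines(sprintf("@attribute class {%s}",
                     paste(DAC_CLASSES, collapse = ",")), con)
  writeLines("@data", con)
  vals <- apply(features, 1L, function(v)
    paste(sprintf("%.17g", v), collapse = ","))
  cls <- ifelse(is.na(labels), "?", labels)
  writeLines(paste(vals, cls, sep = ","), con)
  invisible(path)
}

#' Read back an ARFF file written by [write_arff()]
#'
#' Thin wrapper over [foreign::read.arff()] returning the feature matrix and
#' label vector.
#'
#' @param path ARFF file.
#' @return `list(features=, labels=)`; labels are `NA` where the file had `?`.
#' @export
read_arff_features <- function(path) {
  df <- foreign::read.arff(path)
  cls <- df[["class"]]
  df[["class"]] <- NULL
  list(features = as.matrix(df), labels = as.character(cls))
}

#' Read a survival table
#'
#' TSV with columns `sample_id`, `time`, `event` (1 = death observed).
#'
#' @param path file path.
#' @return data.frame with those three columns.
#' @export
read_survival_table <- function(path) {
  tab <- read.delim(path, header = TRUE)
  names(tab)[1:3] <- c("sample_id", "time", "event")
  if (any(tab$time < 0)) stop("negative survival times")
  if (!all(tab$event %in% c(0, 1))) stop("event must be 0/1")
  tab[, 1:3]
}
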