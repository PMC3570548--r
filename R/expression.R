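#' Construct an expression matrix container
#'
#' Light container for probe- or gene-level expression values: a numeric
#' matrix with unique row identifiers (probes or gene symbols) and unique
#' sample identifiers, tagged with the measurement level and an optional
#' platform name.
#'
#' @param values numeric matrix, rows = probes/genes, columns = samples.
#' @param row_ids character vector of probe or gene identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of sample identifiers; defaults to
#'   `colnames(values)`.
#' @param level `"PROBE"` or `"GENE"`.  Gene-level matrices must have unique
#'   row identifiers; probe-level matrices may not repeat probe ids either,
#'   but many probes may map to one gene via a probe map.
#' @param platform free-text platform name.
#' @return An object of class `expr_matrix`: the numeric matrix with
#'   dimnames set and attributes `level` and `platform`.
#' @export
expression_matrix <- function(values, row_ids = rownames(values),
                              sample_ids = colnames(values),
                              level = c("GENE", "PROBE"), platform = "") {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(row_ids) || is.null(sample_ids))
    stop("row and sample identifiers are required")
  if (length(row_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(row_ids))
    stop("duplicate row identifiers: ",
         paste(unique(row_ids[duplicated(row_ids)])[1:3], collapse = ", "))
  dimnames(values) <- list(as.character(row_ids), as.character(sample_ids))
  structure(values, level = level, platform = platform,
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d %s x %d samples%s\n", nrow(x),
              tolower(attr(x, "level")), ncol(x),
              if (nzchar(attr(x, "platform")))
                paste0(" [", attr(x, "platform"), "]") else ""))
  invisible(x)
}

expr_level <- function(x) attr(x, "level") %||% "GENE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# rebuild container after matrix surgery, keeping metadata
as_expr <- function(values, template, level = expr_level(template)) {
  expression_matrix(values, level = level,
                    platform = attr(template, "platform") %||% "")
}
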