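#' Expression matrices for the three RNA layers
#'
#' A `spng_expr` is a tibble whose first column (`feature`) holds unique
#' feature identifiers and whose remaining columns are per-sample numeric
#' abundances, tagged with a measurement `unit` (`"raw-count"`, `"RPM"`,
#' `"TPM"` or `"FPKM"`) and a `layer` (`"circRNA"`, `"miRNA"` or `"mRNA"`).
#' All pipeline stages accept and return this shape so results chain with
#' the pipe.
#'
#' @param x A data frame (first column feature ids) or a numeric matrix with
#'   rownames as feature ids and colnames as sample ids.
#' @param unit Measurement unit of the values.
#' @param layer RNA layer the features belong to.
#' @return A `spng_expr` tibble.
#' @examples
#' m <- matrix(c(25, 75, 0, 100), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' expr_matrix(m, unit = "raw-count", layer = "mRNA")
#' @export
expr_matrix <- function(x, unit = c("raw-count", "RPM", "TPM", "FPKM"),
                        layer = c("mRNA", "miRNA", "circRNA")) {
  unit <- match.arg(unit)
  layer <- match.arg(layer)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("matrix input needs rownames (feature ids)")
    x <- tibble::as_tibble(x, rownames = "feature")
  }
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L) abort("expression matrix needs a feature column and >= 1 sample")
  names(x)[1] <- "feature"
  x$feature <- as.character(x$feature)
  if (anyDuplicated(x$feature)) abort("duplicate feature ids")
  if (anyDuplicated(names(x))) abort("duplicate sample ids")
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("sample columns must be numeric")
  if (any(!is.finite(vals))) abort("non-finite expression values")
  if (any(vals < 0)) abort("negative expression values")
  new_spng_expr(x, unit, layer)
}

new_spng_expr <- function(tbl, unit, layer) {
  structure(tbl, unit = unit, layer = layer,
            class = c("spng_expr", class(tibble::tibble())))
}

#' @export
print.spng_expr <- function(x, ...) {
  cat(sprintf("# spongenet expression matrix: %d features x %d samples [%s, %s]\n",
              nrow(x), ncol(x) - 1L, expr_layer(x), expr_unit(x)))
  NextMethod()
}

#' Accessors for expression-matrix metadata and values
#'
#' @param x A `spng_expr`.
#' @return `expr_unit()` and `expr_layer()` return the tags; `expr_values()`
#'   the numeric matrix (features in rows); `expr_samples()` the sample ids.
#' @export
expr_unit <- function(x) attr(x, "unit") %||% "raw-count"

#' @rdname expr_unit
#' @export
expr_layer <- function(x) attr(x, "layer") %||% "mRNA"

#' @rdname expr_unit
#' @export
expr_values <- function(x) {
  m <- as.matrix(as.data.frame(x[, -1, drop = FALSE]))
  rownames(m) <- x$feature
  m
}

#' @rdname expr_unit
#' @export
expr_samples <- function(x) names(x)[-1]

assert_raw_counts <- function(x) {
  if (!inherits(x, "spng_expr")) abort("expected a spng_expr (see expr_matrix())")
  if (expr_unit(x) != "raw-count")
    abort(sprintf("expected raw counts, got unit '%s'", expr_unit(x)))
  invisible(x)
}

#' Read and write expression matrices as TSV
#'
#' Tab-separated, first column feature id, header row of sample ids — the
#' dialect the synthetic-data generator emits.
#'
#' @param path File path.
#' @param unit,layer Tags to attach on read (TSV carries no metadata).
#' @param x A `spng_expr` to write.
#' @return `read_expr_tsv()` a `spng_expr`; `write_expr_tsv()` `path`,
#'   invisibly.
#' @export
read_expr_tsv <- function(path, unit = "raw-count", layer = "mRNA") {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  expr_matrix(tbl, unit = unit, layer = layer)
}

#' @rdname read_expr_tsv
#' @export
write_expr_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(as.data.frame(x)), path, progress = FALSE)
  invisible(path)
}

#' Read a two-column feature-length table
#'
#' @param path TSV with columns feature and length (nt).
#' @return A named integer vector of effective lengths.
#' @export
read_lengths_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_names = c("feature", "length"), skip = 1)
  lens <- as.integer(tbl$length)
  if (any(is.na(lens)) || any(lens < 1)) abort("lengths must be positive integers")
  setNames(lens, tbl$feature)
}

write_lengths_tsv <- function(lengths, path) {
  readr::write_tsv(tibble(feature = names(lengths), length = as.integer(lengths)),
                   path, progress = FALSE)
  invisible(path)
}

#' Sample design table
#'
#' Validates a per-sample design (breed, oxygen, replicate) and derives the
#' four group labels used throughout: TN, TL, LN, LL (breed initial +
#' normoxic/hypoxic initial).
#'
#' @param design Data frame with columns `sample`, `breed`
#'   (`"Tibetan"`/`"Landrace"`), `oxygen` (`"normoxic"`/`"hypoxic"`),
#'   `replicate`.
#' @return A tibble with an added `group` column.
#' @export
sample_design <- function(design) {
  design <- tibble::as_tibble(design)
  need <- c("sample", "breed", "oxygen", "replicate")
  if (!all(need %in% names(design)))
    abort(paste("design needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(design$sample)) abort("duplicate sample ids in design")
  if (!all(design$breed %in% c("Tibetan", "Landrace")))
    abort("breed must be 'Tibetan' or 'Landrace'")
  if (!all(design$oxygen %in% c("normoxic", "hypoxic")))
    abort("oxygen must be 'normoxic' or 'hypoxic'")
  design$group <- paste0(substr(design$breed, 1, 1),
                         ifelse(design$oxygen == "normoxic", "N", "L"))
  design
}

design_samples <- function(design, group) {
  design$sample[design$group %in% group]
}
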