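# Readers and writers for the plain-text interchange formats: expression
# TSV (genes as rows, header = sample IDs), GCT 1.2, sample annotations,
# gene lists and JSON-serialized signatures / infiltration models.

#' Read / write a log2 expression matrix as TSV
#'
#' Genes are rows, samples are columns; the first column holds gene
#' symbols and the header line the sample IDs.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_expression_matrix
#' @param x numeric matrix, genes x samples.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write GCT 1.2 expression files
#'
#' The GCT 1.2 format is a TSV with a `#1.2` version line, a dimension
#' line, and NAME / Description columns ahead of the sample columns.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_gct <- function(path) {
  header <- readLines(path, n = 2)
  if (!startsWith(trimws(header[1]), "#1.2")) {
    stop("read_gct: not a GCT 1.2 file (missing #1.2 header)",
         call. = FALSE)
  }
  dims <- as.integer(strsplit(header[2], "\t")[[1]][1:2])
  df <- read.delim(path, skip = 2, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  if (nrow(m) != dims[1] || ncol(m) != dims[2]) {
    warning("read_gct: dimension line (", dims[1], " x ", dims[2],
            ") disagrees with table (", nrow(m), " x ", ncol(m), ")")
  }
  m
}

#' @rdname read_gct
#' @param x numeric matrix, genes x samples.
#' @export
write_gct <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t")), con)
  df <- data.frame(NAME = rownames(x), Description = "na", x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample annotation tables
#'
#' TSV with at least a `sample_id` column; typical columns are `tissue`,
#' `class` (tumor / normal), `p53_status`, `time`, `event`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("read_annotations: missing `sample_id` column", call. = FALSE)
  }
  df
}

#' @rdname read_annotations
#' @param x annotation data.frame.
#' @export
write_annotations <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write plain-text gene lists
#'
#' One symbol per line; `#` starts a comment; blank lines ignored.
#'
#' @param path file path.
#' @param name list name (defaults to the file name).
#' @return a `gene_list` object (see [gene_list()]).
#' @export
read_gene_list <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  genes <- trimws(lines)
  genes <- genes[nzchar(genes)]
  gene_list(name, genes, source = path)
}

#' @rdname read_gene_list
#' @param x a `gene_list` or character vector.
#' @export
write_gene_list <- function(x, path) {
  writeLines(as.character(x), path)
  invisible(path)
}

#' Serialize / restore a PI signature as JSON
#'
#' @param sig a [pi_signature()] object.
#' @param path file path.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "pi_signature"))
  jsonlite::write_json(unclass(sig), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pi_signature(up = x$up, down = x$down, species = x$species,
               expanded = x$expanded, provenance = x$provenance)
}

#' Serialize / restore an infiltration model as JSON
#'
#' @param model an `infiltration_model` from [fit_infiltration_slopes()].
#' @param path file path.
#' @export
write_infiltration_model <- function(model, path) {
  stopifnot(inherits(model, "infiltration_model"))
  out <- list(reference_gene = model$reference_gene,
              genes = rownames(model$slopes),
              tissues = colnames(model$slopes),
              slopes = as.data.frame(model$slopes),
              intercepts = as.data.frame(model$intercepts),
              n_train = as.list(model$n_train))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_infiltration_model
#' @export
read_infiltration_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  slopes <- as.matrix(x$slopes)
  intercepts <- as.matrix(x$intercepts)
  dimnames(slopes) <- dimnames(intercepts) <- list(x$genes, x$tissues)
  structure(list(reference_gene = x$reference_gene,
                 slopes = slopes,
                 intercepts = intercepts,
                 n_train = unlist(x$n_train)),
            class = "infiltration_model")
}
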