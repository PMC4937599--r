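#' Gene lists with provenance
#'
#' A `gene_list` is an ordered, duplicate-free character vector of gene
#' symbols with a name and a provenance string. Symbol comparison
#' throughout the package is case-insensitive (uppercase), but original
#' casing is preserved in outputs.
#'
#' @param name non-empty list name.
#' @param genes character vector of symbols; duplicates (case-insensitive)
#'   are dropped keeping the first occurrence.
#' @param source provenance string.
#' @return a `gene_list` (character vector with attributes).
#' @export
gene_list <- function(name, genes, source = "unspecified") {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop("gene_list: `name` must be a non-empty string", call. = FALSE)
  }
  genes <- as.character(genes)
  genes <- genes[nzchar(genes)]
  genes <- genes[!duplicated(toupper(genes))]
  structure(genes, name = name, source = source, class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat("<gene_list> ", attr(x, "name"), ": ", length(x), " genes (",
      attr(x, "source"), ")\n", sep = "")
  print(head(as.character(x), 10))
  if (length(x) > 10) cat("...\n")
  invisible(x)
}

#' @export
`[.gene_list` <- function(x, i) {
  gene_list(attr(x, "name"), unclass(x)[i], attr(x, "source"))
}

#' Assemble the inflammatory-response gene universe by list voting
#'
#' Combines curated inflammatory / innate-immunity gene lists, keeping
#' genes present in at least `min_votes` of them. Symbols are compared
#' case-insensitively; the first-seen casing is kept. Applied to the
#' Ingenuity, InnateDB and IRIS databases this voting yields the 840-gene
#' inflammatory-response universe used to derive the PI signature.
#'
#' @param lists a list of [gene_list()]s (or character vectors).
#' @param min_votes minimum number of lists a gene must appear in.
#' @return a `gene_list` of the voted universe, sorted.
#' @export
assemble_inflammatory_genes <- function(lists, min_votes = 2) {
  if (length(lists) < min_votes) {
    stop("assemble_inflammatory_genes: fewer lists (", length(lists),
         ") than min_votes (", min_votes, ")", call. = FALSE)
  }
  per_list <- lapply(lists, function(l) unique(toupper(as.character(l))))
  votes <- table(unlist(per_list))
  keep_upper <- names(votes)[votes >= min_votes]
  # recover first-seen original casing
  all_orig <- unlist(lapply(lists, as.character), use.names = FALSE)
  first_case <- all_orig[!duplicated(toupper(all_orig))]
  names(first_case) <- toupper(first_case)
  out <- sort(unname(first_case[keep_upper]))
  gene_list("inflammatory_universe", out,
            source = sprintf("voting >=%d of %d lists", min_votes,
                             length(lists)))
}

#' Map gene symbols across species
#'
#' Translates signature gene symbols (e.g., mouse to human) through a
#' two-column symbol table. Unmapped genes are dropped with a warning and
#' recorded in the result's provenance.
#'
#' @param sig a [pi_signature()] or character vector of symbols.
#' @param mapping data.frame with columns `from` and `to`.
#' @return same class as `sig` with symbols translated; a `pi_signature`
#'   has its `species` flag flipped and unmapped genes listed in
#'   `provenance$unmapped`.
#' @export
map_orthologs <- function(sig, mapping) {
  stopifnot(is.data.frame(mapping), all(c("from", "to") %in% names(mapping)))
  lut <- setNames(as.character(mapping$to), toupper(mapping$from))
  translate <- function(genes) {
    hit <- lut[toupper(genes)]
    miss <- genes[is.na(hit)]
    if (length(miss)) {
      warning("map_orthologs: no mapping for ",
              paste(miss, collapse = ", "))
    }
    list(mapped = unname(hit[!is.na(hit)]), unmapped = miss)
  }
  if (inherits(sig, "pi_signature")) {
    up <- translate(sig$up)
    down <- translate(sig$down)
    pi_signature(up = up$mapped, down = down$mapped,
                 species = setdiff(c("human", "mouse"), sig$species)[1],
                 expanded = sig$expanded,
                 provenance = c(sig$provenance,
                                list(unmapped = c(up$unmapped,
                                                  down$unmapped))))
  } else {
    translate(as.character(sig))$mapped
  }
}
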