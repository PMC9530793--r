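#' OTU abundance table container
#'
#' Holds per-individual OTU relative abundances (each individual's profile
#' sums to 1) plus the taxonomy of each OTU down to genus. Counts are
#' accepted and renormalized; the internal unit is always a proportion.
#'
#' @param abundance numeric matrix, OTUs in rows, individuals in columns,
#'   non-negative; columns are renormalized to sum to 1.
#' @param otu_ids,individual_ids character vectors naming rows / columns.
#' @param taxonomy data.frame with columns `otu_id`, `phylum`, `class`,
#'   `order`, `family`, `genus`; unassigned ranks hold `"unclassified"`.
#' @param counts optional integer matrix of raw read counts (same shape),
#'   kept for diversity estimators that need singleton/doubleton counts.
#' @return An object of class `holo_otu`.
#' @export
otu_abundance <- function(abundance, otu_ids, individual_ids, taxonomy,
                          counts = NULL) {
  abundance <- as.matrix(abundance)
  if (any(abundance < 0))
    stop_hologreml("negative abundance", "hologreml_validation_error")
  if (anyDuplicated(otu_ids) || anyDuplicated(individual_ids))
    stop_hologreml("duplicate OTU or individual ids",
                   "hologreml_validation_error")
  cs <- colSums(abundance)
  if (any(cs == 0))
    stop_hologreml(
      paste0("individual(s) with all-zero abundance: ",
             paste(individual_ids[cs == 0], collapse = ", ")),
      "hologreml_validation_error")
  abundance <- sweep(abundance, 2, cs, "/")
  dimnames(abundance) <- list(otu_ids, individual_ids)
  taxonomy <- taxonomy[match(otu_ids, taxonomy$otu_id), , drop = FALSE]
  rownames(taxonomy) <- NULL
  structure(list(abundance = abundance,
                 otu_ids = as.character(otu_ids),
                 individual_ids = as.character(individual_ids),
                 taxonomy = taxonomy,
                 counts = counts),
            class = "holo_otu")
}

#' @export
print.holo_otu <- function(x, ...) {
  cat(sprintf("<holo_otu> %d OTUs x %d individuals (%d genera annotated)\n",
              length(x$otu_ids), length(x$individual_ids),
              length(setdiff(unique(x$taxonomy$genus), "unclassified"))))
  invisible(x)
}

TAX_RANKS <- c("phylum", "class", "order", "family", "genus")

#' Parse Greengenes-style taxonomy strings
#'
#' `"p__Firmicutes; c__...; g__Streptococcus"` is split on `;`, rank
#' prefixes (`k__`, `p__`, ...) are stripped, and empty or absent ranks
#' become `"unclassified"`. Only phylum..genus are retained.
#'
#' @param strings character vector of lineage strings.
#' @return data.frame with columns phylum, class, order, family, genus.
#' @export
parse_taxonomy <- function(strings) {
  prefix_of <- c(phylum = "p", class = "c", order = "o", family = "f",
                 genus = "g")
  out <- lapply(strings, function(s) {
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    vals <- vapply(TAX_RANKS, function(r) {
      hit <- grep(paste0("^", prefix_of[[r]], "__"), parts, value = TRUE)
      v <- if (length(hit)) sub("^.__", "", hit[1]) else ""
      if (nzchar(v)) v else "unclassified"
    }, character(1))
    vals
  })
  as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
}

#' Read an OTU table
#'
#' TSV dialect: OTUs in rows, one column per individual, plus a `taxonomy`
#' column holding the Greengenes-style lineage string. BIOM dialect: a
#' (JSON) BIOM file read through the biomformat package, with taxonomy
#' taken from the per-observation metadata. Count input is renormalized to
#' proportions per individual; the raw counts are retained when integral.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @param orientation for TSV, `"otus_in_rows"` (default) or
#'   `"individuals_in_rows"`.
#' @return A `holo_otu`.
#' @export
read_otu_table <- function(path, format = c("tsv", "biom"),
                           orientation = c("otus_in_rows",
                                           "individuals_in_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    stop_hologreml(paste0("file not found: ", path), "hologreml_io_error")

  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop_hologreml("biomformat package required for BIOM input",
                     "hologreml_io_error")
    b <- biomformat::read_biom(path)
    mat <- as(biomformat::biom_data(b), "matrix")
    md <- biomformat::observation_metadata(b)
    tax_strings <- if (is.data.frame(md)) {
      apply(md, 1, paste, collapse = "; ")
    } else {
      vapply(md, function(x) paste(unlist(x), collapse = "; "), character(1))
    }
    tax <- parse_taxonomy(tax_strings)
    tax$otu_id <- rownames(mat)
    counts <- if (all(mat == round(mat))) mat else NULL
    return(otu_abundance(mat, rownames(mat), colnames(mat), tax,
                         counts = counts))
  }

  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "")
  if (orientation == "individuals_in_rows") {
    # first column = individual id; no taxonomy column possible
    ids <- as.character(df[[1]])
    mat <- t(as.matrix(df[, -1, drop = FALSE]))
    colnames(mat) <- ids
    tax <- data.frame(otu_id = rownames(mat))
    for (r in TAX_RANKS) tax[[r]] <- "unclassified"
    counts <- if (all(mat == round(mat))) mat else NULL
    return(otu_abundance(mat, rownames(mat), ids, tax, counts = counts))
  }
  otu_ids <- as.character(df[[1]])
  tax_col <- which(names(df) == "taxonomy")
  if (length(tax_col)) {
    tax <- parse_taxonomy(df[[tax_col]])
    df <- df[, -tax_col, drop = FALSE]
  } else {
    tax <- as.data.frame(matrix("unclassified", nrow(df), length(TAX_RANKS),
                                dimnames = list(NULL, TAX_RANKS)),
                         stringsAsFactors = FALSE)
  }
  tax$otu_id <- otu_ids
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- otu_ids
  counts <- if (all(mat == round(mat))) mat else NULL
  otu_abundance(mat, otu_ids, colnames(mat), tax, counts = counts)
}

#' Write an OTU table as TSV
#'
#' Writes proportions (OTUs in rows) with a trailing `taxonomy` column in
#' the Greengenes prefix style, round-trippable through [read_otu_table()].
#'
#' @param otu a `holo_otu`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(otu, path) {
  tax <- otu$taxonomy
  lineage <- paste0("p__", ifelse(tax$phylum == "unclassified", "", tax$phylum),
                    "; c__", ifelse(tax$class == "unclassified", "", tax$class),
                    "; o__", ifelse(tax$order == "unclassified", "", tax$order),
                    "; f__", ifelse(tax$family == "unclassified", "", tax$family),
                    "; g__", ifelse(tax$genus == "unclassified", "", tax$genus))
  df <- data.frame(otu_id = otu$otu_ids,
                   otu$abundance,
                   taxonomy = lineage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
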