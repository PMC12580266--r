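#' Expression matrices
#'
#' Thin container around a genes x samples matrix that remembers whether the
#' values are raw integer counts or normalized (nonnegative real) values.
#'
#' @param counts numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs).
#' @param normalized logical; `FALSE` for raw integer counts.
#' @return An `expression_matrix`: the matrix with a `normalized` attribute.
#' @export
expression_matrix <- function(counts, normalized = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (any(counts < 0)) stop("negative entries in expression matrix")
  if (!normalized && any(counts != round(counts)))
    stop("raw counts must be integers")
  structure(counts, normalized = normalized, class = c("expression_matrix",
                                                       class(counts)))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "normalized"))) "normalized" else
                "raw counts"))
  invisible(x)
}

read_tsv_checked <- function(path, cols, colClasses) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(path, ": missing column(s): ", paste(missing, collapse = ", "))
  df[cols]
}

fail_rows <- function(bad, path, what) {
  if (any(bad))
    stop(path, ": ", what, " at line ",
         paste(utils::head(which(bad) + 1L, 5L), collapse = ", "),
         if (sum(bad) > 5L) sprintf(" (and %d more)", sum(bad) - 5L) else "")
}

#' Read a gene-by-sample count table
#'
#' TSV with header `gene_id<TAB>sample1<TAB>...`; integer cells for raw
#' counts. If a design is supplied the sample columns must match its sample
#' list exactly.
#'
#' @param path TSV path.
#' @param design optional [cross_design()] to validate sample IDs against.
#' @param normalized logical; set `TRUE` when reading normalized values.
#' @return An [expression_matrix()].
#' @export
read_counts <- function(path, design = NULL, normalized = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "gene_id")
    stop(path, ": first column must be gene_id")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df$gene_id
  if (any(is.na(mat))) stop(path, ": non-numeric or missing count cells")
  if (!is.null(design)) {
    if (!setequal(colnames(mat), design$samples$sample))
      stop(path, ": sample columns do not match the design sample list")
    mat <- mat[, design$samples$sample, drop = FALSE]
  }
  expression_matrix(mat, normalized = normalized)
}

#' Write a count table
#' @param expr an [expression_matrix()] (or plain matrix).
#' @param path output TSV path.
#' @export
write_counts <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), as.data.frame(unclass(expr)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-SNP allelic read counts
#'
#' Columns: `gene_id, chrom, pos, allele_a, allele_b, reads_a, reads_b,
#' sample`. Allele labels are genotypes of origin (e.g. L2/L4), never
#' maternal/paternal: parent-of-origin is resolved per cross through the
#' design. A SNP assigned to more than one gene (overlapping annotations) is
#' accepted and flagged in the `dup_assignment` column.
#'
#' @param path TSV path.
#' @return data.frame of validated records.
#' @export
read_allele_counts <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "chrom", "pos", "allele_a",
                                 "allele_b", "reads_a", "reads_b", "sample"))
  for (cc in c("pos", "reads_a", "reads_b"))
    df[[cc]] <- as.integer(df[[cc]])
  fail_rows(is.na(df$reads_a) | is.na(df$reads_b) | is.na(df$pos),
            path, "non-integer pos/reads field")
  fail_rows(df$reads_a < 0 | df$reads_b < 0, path, "negative read count")
  key_snp <- paste(df$chrom, df$pos, df$sample)
  dup <- stats::ave(df$gene_id, key_snp,
                    FUN = function(g) length(unique(g))) != "1"
  df$dup_assignment <- as.logical(dup)
  if (any(dup))
    warning(sum(dup & !duplicated(paste(key_snp, df$gene_id))),
            " SNP records assigned to more than one gene (flagged)")
  df
}

#' Read allele-resolved per-cytosine methylation calls
#'
#' Columns: `chrom, pos, strand, context, allele, meth_reads, total_reads,
#' sample`; context must be CG, CHG or CHH; `meth_reads <= total_reads`.
#'
#' @param path TSV path.
#' @return data.frame of validated calls.
#' @export
read_methyl_calls <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "pos", "strand", "context",
                                 "allele", "meth_reads", "total_reads",
                                 "sample"))
  for (cc in c("pos", "meth_reads", "total_reads"))
    df[[cc]] <- as.integer(df[[cc]])
  fail_rows(is.na(df$meth_reads) | is.na(df$total_reads), path,
            "non-integer read field")
  fail_rows(df$meth_reads < 0 | df$total_reads < 0, path,
            "negative read count")
  fail_rows(df$meth_reads > df$total_reads, path,
            "meth_reads greater than total_reads")
  fail_rows(!df$context %in% c("CG", "CHG", "CHH"), path,
            "unknown methylation context")
  fail_rows(!df$strand %in% c("+", "-"), path, "bad strand")
  df
}

#' Read gene annotation (BED6 or GFF3)
#'
#' Parses with `rtracklayer::import` (BED's 0-based half-open intervals are
#' converted to 1-based closed on load). Coordinates are normalized to
#' transcription order: `tss` is the transcription start (the interval end on
#' the minus strand) and `tts` the transcription end, so `tss` -> `tts`
#' always runs 5' to 3'. For GFF3 only `gene` features are kept.
#'
#' @param path `.bed`, `.gff` or `.gff3` file.
#' @return data.frame with columns `gene_id, chrom, strand, tss, tts`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- gr$name
  } else if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "GFF3")
    gr <- gr[gr$type == "gene"]
    ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
  } else stop("unsupported annotation format: .", ext)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stop(path, ": annotation entries must be stranded (+/-)")
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop(path, ": every gene needs an ID/name")
  st <- BiocGenerics::start(gr)
  en <- BiocGenerics::end(gr)
  data.frame(
    gene_id = ids,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    strand = strand,
    tss = ifelse(strand == "+", st, en),
    tts = ifelse(strand == "+", en, st)
  )
}

#' Write any result table as TSV
#'
#' Plain TSV, no quoting, no row names, stable column order as given:
#' reading a table written by this function reproduces every field.
#'
#' @param results data.frame.
#' @param path output path.
#' @export
write_table <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
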