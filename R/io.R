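# Plain-text readers and writers: expression/count matrices as TSV
# (first column gene id, header row of sample ids), gene sets as GMT,
# gene annotation as BED6 plus a biotype column, structured results as
# JSON.

#' Read an expression (or count) matrix from TSV
#'
#' First column gene ids, header row sample ids. Rejects ragged rows,
#' duplicated ids, and non-numeric cells; tolerant of Windows line
#' endings.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stopf("matrix file needs a header and >= 1 row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  n_col <- length(header)
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) stopf("duplicate sample ids in header")
  body <- cells[-1]
  ragged <- which(lengths(body) != n_col)
  if (length(ragged))
    stopf("ragged row at line %d (expected %d fields, got %d)",
          ragged[1] + 1L, n_col, lengths(body)[ragged[1]])
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  dup <- which(duplicated(gene_ids))
  if (length(dup))
    stopf("duplicate gene id '%s' at line %d", gene_ids[dup[1]], dup[1] + 1L)
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1]), numeric(n_col - 1L)))
  vals <- matrix(vals, ncol = length(body))  # guard 1-sample case
  if (any(is.na(vals))) {
    bad <- which(colSums(is.na(vals)) > 0)[1]
    stopf("non-numeric cell at line %d", bad + 1L)
  }
  matrix(t(vals), nrow = length(gene_ids),
         dimnames = list(gene_ids, sample_ids))
}

#' Write an expression matrix as TSV
#'
#' @param expr Matrix with dimnames.
#' @param path Output path.
#' @param id_column Header label for the gene-id column.
#' @export
write_expression_tsv <- function(expr, path, id_column = "gene_id") {
  check_expression_matrix(expr)
  df <- data.frame(expr[, , drop = FALSE], check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(expr)), id_column), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: tab-separated name, description, then members. Lines
#' with fewer than three fields (including empty member lists) are an
#' error.
#'
#' @param path File path.
#' @return Named list of character vectors; descriptions kept as the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(cells) < 3L)
  if (length(short)) stopf("GMT line %d has fewer than 3 fields", short[1])
  sets <- lapply(cells, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(cells, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stopf("duplicate set names in GMT")
  attr(sets, "descriptions") <-
    stats::setNames(vapply(cells, `[[`, character(1), 2L), names(sets))
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors (no empty sets).
#' @param path Output path.
#' @param descriptions Optional named descriptions (default ".").
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets))) stopf("`sets` must be named")
  if (any(lengths(sets) == 0L)) stopf("empty gene set cannot be written")
  desc <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(rep(".", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]] %||% ".", sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotation from BED6 + biotype
#'
#' Columns: chrom, start, end, name, score, strand, biotype (0-based
#' half-open coordinates). Records are validated and sorted by
#' chromosome, start, end, then gene id.
#'
#' @param path File path.
#' @return Data frame: chrom, start, end, strand, gene_id, biotype, score.
#' @export
read_bed_annotation <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(cells) < 7L)
  if (length(short)) stopf("BED line %d has fewer than 7 fields", short[1])
  df <- data.frame(
    chrom = vapply(cells, `[[`, character(1), 1L),
    start = as.integer(vapply(cells, `[[`, character(1), 2L)),
    end = as.integer(vapply(cells, `[[`, character(1), 3L)),
    strand = vapply(cells, `[[`, character(1), 6L),
    gene_id = vapply(cells, `[[`, character(1), 4L),
    biotype = vapply(cells, `[[`, character(1), 7L),
    score = vapply(cells, `[[`, character(1), 5L),
    stringsAsFactors = FALSE)
  if (any(is.na(df$start)) || any(is.na(df$end))) stopf("non-integer coordinates")
  bad <- which(df$start >= df$end)
  if (length(bad)) stopf("start >= end at line %d", bad[1])
  if (!all(df$strand %in% c("+", "-", "."))) stopf("unknown strand symbol")
  if (anyDuplicated(df$gene_id)) stopf("duplicate gene ids in annotation")
  df <- df[order(df$chrom, df$start, df$end, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write gene annotation as BED6 + biotype
#'
#' @param annot Annotation data frame (chrom, start, end, strand,
#'   gene_id, biotype, optional score).
#' @param path Output path.
#' @export
write_bed_annotation <- function(annot, path) {
  score <- annot$score %||% rep(0, nrow(annot))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s",
                   annot$chrom, annot$start, annot$end, annot$gene_id,
                   as.character(score), annot$strand, annot$biotype)
  writeLines(lines, path)
  invisible(path)
}
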