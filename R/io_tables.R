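#' Read and write the package's tab-separated tables
#'
#' Gene tables are TSV with header columns `gene_id`, `chrom`, `start`,
#' `end`, `strand`, `expression`; DSB sites are 6-column BED
#' (`name` = dsb_id, `score` = cleavage x 1000); annotations are TSV with
#' header `dsb_id`, `gene_id`, `tc`, `position_class`, `exon_class`.
#'
#' @param path File path.
#' @return The parsed table.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_gene_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_table(g$gene_id, g$chrom, g$start, g$end, g$strand, g$expression)
}

#' @rdname table_io
#' @param genes A [gene_table()].
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_dsb_bed <- function(path) {
  b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(b) < 6) stop("DSB BED must have 6 columns")
  names(b)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (anyDuplicated(b$name)) stop("dsb_id (BED name) must be unique")
  data.frame(dsb_id = b$name, chrom = b$chrom, cut = b$start,
             cleavage = b$score / 1000, stringsAsFactors = FALSE)
}

#' @rdname table_io
#' @param dsbs data.frame with `dsb_id`, `chrom`, `cut`, `cleavage`.
#' @export
write_dsb_bed <- function(dsbs, path) {
  bed <- data.frame(chrom = dsbs$chrom, start = dsbs$cut,
                    end = dsbs$cut + 1, name = dsbs$dsb_id,
                    score = round(dsbs$cleavage * 1000), strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @param annotations Annotation data.frame (see [classify_dsbs()]).
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_annotations <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("dsb_id", "gene_id", "tc", "position_class", "exon_class")
  if (!all(need %in% names(a))) {
    stop("annotation table must have columns: ",
         paste(need, collapse = ", "))
  }
  a$tc <- as.logical(a$tc)
  a
}

#' Packaged DSB annotation fixture
#'
#' Loads the synthetic DSB annotation table shipped with the package.
#' The table is a constructed stand-in for a published manual annotation
#' of 80 restriction-enzyme-induced break sites (the original
#' supplementary table is not redistributable here): it reproduces every
#' published category total — 80 sites, 65 transcription-coupled and 15
#' silent; 31 promoter, 36 five-prime and 9 gene-body annotations; 19
#' exonic and 26 intronic; 11 dual-annotated sites — while site/gene
#' identifiers and the pairing of labels to sites are synthetic.
#'
#' @return Annotation data.frame (see [classify_dsbs()]).
#' @export
load_dsb_annotation_fixture <- function() {
  path <- system.file("extdata", "dsb_annotations_synthetic.tsv",
                      package = "dsbstrand", mustWork = TRUE)
  read_annotations(path)
}
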