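#' Read exon records from a GTF file into a transcript table
#'
#' Parses a GTF annotation and returns one row per exon of every transcript,
#' keeping only `feature == "exon"` records. Coordinates stay in the GTF
#' convention (1-based, closed intervals).
#'
#' @param path Path to a GTF file.
#' @return A data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` (1-based closed).
#' @export
read_gtf_exons <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon records found in ", path)
  data.frame(
    gene_id       = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    chrom         = as.character(GenomicRanges::seqnames(gr)),
    strand        = as.character(GenomicRanges::strand(gr)),
    start         = GenomicRanges::start(gr),
    end           = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# exon table for one gene -> list of per-transcript IRanges (1-based closed)
.split_transcripts <- function(exons) {
  lapply(split(exons, exons$transcript_id), function(e) {
    ir <- IRanges::IRanges(start = e$start, end = e$end)
    IRanges::reduce(ir)
  })
}

.check_single_gene <- function(exons) {
  gid <- unique(exons$gene_id)
  if (length(gid) != 1L) stop("exon table spans several genes: ",
                              paste(gid, collapse = ", "))
  if (length(unique(exons$chrom)) != 1L)
    stop("gene ", gid, " has exons on several chromosomes")
  if (length(unique(exons$strand)) != 1L)
    stop("gene ", gid, " has exons on both strands")
  gid
}

#' Merge all transcripts of a gene into a gene body
#'
#' The gene body is the union of the transcript spans (each transcript
#' contributes the interval from its first to its last exonic base), so
#' disjoint transcripts yield a multi-interval gene body.
#'
#' @param exons data.frame of exons for one gene (columns `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `start`, `end`; 1-based closed).
#' @return An [IRanges::IRanges] with the merged gene-body intervals.
#' @export
merge_gene_body <- function(exons) {
  .check_single_gene(exons)
  tx <- .split_transcripts(exons)
  spans <- do.call(c, unname(lapply(tx, range)))
  IRanges::reduce(spans)
}

#' Build exonic and intronic region sets for one gene
#'
#' A base is exonic if it lies in an exon of at least one transcript. A base
#' is intronic if it is intronic (inside the transcript span but not in an
#' exon) in every transcript whose span covers it, and exonic in none.
#' Bases of the gene body covered by no transcript span (possible only with
#' disjoint transcripts) are neither.
#'
#' @inheritParams merge_gene_body
#' @return A list with `gene_id`, `chrom`, `strand`, `exonic` and `intronic`
#'   ([IRanges::IRanges], 1-based closed), and `exonic_length`,
#'   `intronic_length` in bp.
#' @export
build_gene_regions <- function(exons) {
  if (nrow(exons) == 0L) stop("empty exon table")
  gid <- .check_single_gene(exons)
  tx <- .split_transcripts(exons)

  exonic <- IRanges::reduce(do.call(c, unname(tx)))
  # per-transcript intronic = span minus exons; union over transcripts,
  # then remove anything exonic anywhere
  intr_tx <- lapply(tx, function(ir) IRanges::setdiff(range(ir), ir))
  intronic <- IRanges::reduce(do.call(c, unname(intr_tx)))
  intronic <- IRanges::setdiff(intronic, exonic)

  list(
    gene_id = gid,
    chrom = unique(exons$chrom),
    strand = unique(exons$strand),
    exonic = exonic,
    intronic = intronic,
    exonic_length = sum(IRanges::width(exonic)),
    intronic_length = sum(IRanges::width(intronic))
  )
}

#' Build regions for every gene in an exon table
#'
#' @param exons data.frame of exons across genes (see [read_gtf_exons()]).
#' @return Named list of per-gene region sets from [build_gene_regions()].
#' @export
build_all_gene_regions <- function(exons) {
  lapply(split(exons, exons$gene_id), build_gene_regions)
}

#' Tabulate exonic and intronic lengths per gene
#'
#' @param regions List of region sets from [build_all_gene_regions()].
#' @return data.frame with `gene_id`, `exonic_length`, `intronic_length`.
#' @export
region_lengths <- function(regions) {
  data.frame(
    gene_id = vapply(regions, `[[`, "", "gene_id"),
    exonic_length = vapply(regions, `[[`, 0, "exonic_length"),
    intronic_length = vapply(regions, `[[`, 0, "intronic_length"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write regions as a BED-like table (0-based half-open)
#'
#' @param regions List from [build_all_gene_regions()].
#' @param path Output TSV path.
#' @export
write_regions_bed <- function(regions, path) {
  rows <- lapply(regions, function(r) {
    out <- list()
    for (lay in c("exonic", "intronic")) {
      ir <- r[[lay]]
      if (length(ir) == 0L) next
      out[[lay]] <- data.frame(
        chrom = r$chrom,
        start = IRanges::start(ir) - 1L,  # 1-based closed -> 0-based half-open
        end = IRanges::end(ir),
        gene_id = r$gene_id,
        layer = lay,
        strand = r$strand,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
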