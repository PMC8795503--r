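#' Read a UCSC chrom.sizes file into a Seqinfo
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path path to the chrom.sizes file.
#' @return a [GenomeInfoDb::Seqinfo] describing the genome layout.
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.delim(path, header = FALSE, col.names = c("chrom", "length"),
                    colClasses = c("character", "integer"))
  if (nrow(tab) == 0L) stop("empty chrom.sizes file: ", path)
  if (any(tab$length <= 0L)) stop("chromosome lengths must be > 0")
  Seqinfo(seqnames = tab$chrom, seqlengths = tab$length)
}

#' Write a Seqinfo as a chrom.sizes file
#'
#' @param seqinfo a [GenomeInfoDb::Seqinfo].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(seqinfo, path) {
  write.table(data.frame(seqlevels(seqinfo), seqlengths(seqinfo)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of genomic regions
#'
#' BED3/BED6, 0-based half-open on disk, converted to 1-based closed
#' `GRanges` on read. If the name field holds `"gain"`/`"loss"` it is
#' carried as a `cnc_class` metadata column (copy-number-change class).
#'
#' @param path BED file path.
#' @param genome optional [GenomeInfoDb::Seqinfo]; when given, regions are
#'   bounds-checked against it and the result carries its seqinfo.
#' @return a `GRanges`.
#' @export
read_bed <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gr$name) && all(gr$name %in% c("gain", "loss"))) {
    mcols(gr)$cnc_class <- gr$name
  }
  if (!is.null(genome)) {
    gr <- .with_seqinfo(gr, genome)
  }
  gr
}

#' Write regions as a BED file
#'
#' Emits BED6 when a `cnc_class` column is present (class in the name
#' field, `score` column in the score field if available), BED3 otherwise.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  out <- gr
  if (!is.null(mcols(gr)$cnc_class)) {
    mcols(out)$name <- mcols(gr)$cnc_class
  }
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read a bedGraph coverage file as a per-base RleList track
#'
#' @param path bedGraph path (4 columns, 0-based half-open intervals).
#' @param genome optional [GenomeInfoDb::Seqinfo]; when given the track
#'   spans full chromosomes (zero-filled outside covered intervals).
#' @return a named `RleList`, one nonnegative per-base `Rle` per chromosome.
#' @export
read_bedgraph <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(gr$score < 0)) stop("coverage tracks must be nonnegative: ", path)
  if (!is.null(genome)) gr <- .with_seqinfo(gr, genome)
  coverage(gr, weight = gr$score)
}

#' Write an RleList coverage track as bedGraph
#'
#' @param track an `RleList` as returned by [read_bedgraph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  runs <- do.call(rbind, lapply(names(track), function(chr) {
    r <- track[[chr]]
    n <- S4Vectors::nrun(r)
    data.frame(chrom = chr, start = cumsum(c(1L, runLength(r)[-n])),
               width = runLength(r), score = as.numeric(runValue(r)))
  }))
  runs <- runs[runs$score != 0, , drop = FALSE]
  gr <- GRanges(runs$chrom, IRanges(runs$start, width = runs$width),
                score = runs$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# Attach seqinfo and fail loudly if any interval falls outside the layout.
.with_seqinfo <- function(gr, genome) {
  bad <- !(as.character(seqnames(gr)) %in% seqlevels(genome))
  if (any(bad)) {
    stop("chromosome(s) absent from genome layout: ",
         paste(unique(as.character(seqnames(gr))[bad]), collapse = ", "))
  }
  seqlevels(gr) <- seqlevels(genome)
  seqinfo(gr) <- genome
  lens <- seqlengths(genome)[as.character(seqnames(gr))]
  if (any(start(gr) < 1L) || any(end(gr) > lens)) {
    stop("interval outside chromosome bounds")
  }
  gr
}

#' Read a gene-model table
#'
#' Tab-separated with header and columns `gene_id`, `chrom`, `strand`,
#' `tss`, `tes` (1-based positions). On the `+` strand `tss < tes`; on the
#' `-` strand `tss > tes`.
#'
#' @param path TSV path.
#' @return a validated gene-model `data.frame` with an added `length_bp`.
#' @export
read_gene_table <- function(path) {
  genes <- read.delim(path, stringsAsFactors = FALSE)
  validate_genes(genes)
}

#' Validate (and normalize) a gene-model data.frame
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `tss`, `tes`.
#' @return the data.frame with `length_bp = abs(tes - tss) + 1` appended.
#' @export
validate_genes <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "tss", "tes")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(genes$tss == genes$tes)) stop("tss must differ from tes")
  plus <- genes$strand == "+"
  if (any(genes$tss[plus] > genes$tes[plus]) ||
      any(genes$tss[!plus] < genes$tes[!plus])) {
    stop("tss/tes order inconsistent with strand")
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  genes$length_bp <- abs(genes$tes - genes$tss) + 1L
  genes
}

#' Write a gene-model table
#' @param genes gene-model data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene bodies as GRanges
#'
#' The genic interval spans TSS to TES inclusive, whatever the strand.
#'
#' @param genes gene-model data.frame.
#' @param genome optional `Seqinfo`.
#' @return a `GRanges` named by `gene_id`, stranded.
#' @export
gene_body_granges <- function(genes, genome = NULL) {
  gr <- GRanges(genes$chrom,
                IRanges(pmin(genes$tss, genes$tes),
                        pmax(genes$tss, genes$tes)),
                strand = genes$strand)
  names(gr) <- genes$gene_id
  if (!is.null(genome)) gr <- .with_seqinfo(gr, genome)
  gr
}

#' TSS positions as width-1 GRanges
#' @inheritParams gene_body_granges
#' @return a width-1 `GRanges` named by `gene_id`.
#' @export
tss_granges <- function(genes, genome = NULL) {
  gr <- GRanges(genes$chrom, IRanges(genes$tss, width = 1L),
                strand = genes$strand)
  names(gr) <- genes$gene_id
  if (!is.null(genome)) gr <- .with_seqinfo(gr, genome)
  gr
}

#' Read an aCGH probe table
#'
#' Tab-separated with header and columns `chrom`, `pos` (bp, 1-based),
#' `log2_ratio`. Positions must be strictly increasing within each
#' chromosome and ratios finite.
#'
#' @param path TSV path.
#' @return a validated probe `data.frame`.
#' @export
read_probe_table <- function(path) {
  probes <- read.delim(path, stringsAsFactors = FALSE)
  validate_probes(probes)
}

#' Validate an aCGH probe table
#' @param probes data.frame with `chrom`, `pos`, `log2_ratio`.
#' @return the validated data.frame.
#' @export
validate_probes <- function(probes) {
  need <- c("chrom", "pos", "log2_ratio")
  miss <- setdiff(need, names(probes))
  if (length(miss)) stop("probe table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(probes$log2_ratio))) stop("non-finite log2_ratio")
  ok <- unlist(tapply(probes$pos, probes$chrom,
                      function(p) length(p) < 2L || all(diff(p) > 0)),
               use.names = FALSE)
  if (!all(ok)) stop("probe positions must be strictly increasing per chromosome")
  probes
}

#' Read a qPCR Ct table
#'
#' Tab-separated with header and columns `sample`, `region`, `antibody`
#' (`specific`, `IgG` or `input`), `replicate`, `ct`, `input_fraction`.
#'
#' @param path TSV path.
#' @return a validated Ct `data.frame`.
#' @export
read_ct_table <- function(path) {
  ct <- read.delim(path, stringsAsFactors = FALSE)
  validate_ct_table(ct)
}

#' Validate a qPCR Ct table
#' @param ct data.frame as described in [read_ct_table()].
#' @return the validated data.frame.
#' @export
validate_ct_table <- function(ct) {
  need <- c("sample", "region", "antibody", "replicate", "ct",
            "input_fraction")
  miss <- setdiff(need, names(ct))
  if (length(miss)) stop("Ct table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(ct$antibody %in% c("specific", "IgG", "input"))) {
    stop("antibody must be one of 'specific', 'IgG', 'input'")
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    stop("Ct values must be finite and > 0")
  }
  if (any(ct$input_fraction <= 0 | ct$input_fraction > 1)) {
    stop("input_fraction must be in (0, 1]")
  }
  ct
}
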