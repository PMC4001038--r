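# Gene/operon coordinate model shared by both fitness pipelines.
#
# Coordinates are 1-based inclusive in all files (GFF3 dialect); internal
# window arithmetic uses 0-based offsets from the gene's 5' end and converts
# back only at the boundary, so there is a single conversion point.

#' Construct a validated genome annotation
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`+`/`-`), and optionally `operon_id` (NA allowed) and
#'   `is_pseudo` (logical). Coordinates are 1-based inclusive.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp;
#'   inferred as `max(end)` per chromosome when omitted.
#' @return a `tn_annotation`: the gene table sorted by (chrom, start) with a
#'   `chrom_lengths` attribute.
#' @export
tn_annotation <- function(genes, chrom_lengths = NULL) {
  req <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(genes))
  if (length(miss))
    stop_tn("annotation is missing column(s): %s", paste(miss, collapse = ", "))
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- as.character(genes$strand)
  if (is.null(genes$operon_id)) genes$operon_id <- NA_character_
  genes$operon_id <- as.character(genes$operon_id)
  if (is.null(genes$is_pseudo)) genes$is_pseudo <- FALSE
  genes$is_pseudo <- as.logical(genes$is_pseudo)

  bad <- which(!genes$strand %in% c("+", "-"))
  if (length(bad))
    stop_tn("invalid strand in row(s) %s", paste(bad, collapse = ", "))
  bad <- which(genes$end < genes$start)
  if (length(bad))
    stop_tn("end < start in row(s) %s", paste(bad, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop_tn("duplicated gene_id: %s",
            paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))

  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(genes$end, genes$chrom), max, numeric(1))
  }
  out <- which(genes$end > chrom_lengths[genes$chrom] | genes$start < 1L)
  if (length(out))
    stop_tn("gene(s) outside chromosome bounds in row(s) %s",
            paste(out, collapse = ", "))

  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(genes,
            chrom_lengths = chrom_lengths,
            class = c("tn_annotation", "data.frame"))
}

#' Chromosome lengths of an annotation
#' @param ann a `tn_annotation`.
#' @return named numeric vector of lengths in bp.
#' @export
chrom_lengths <- function(ann) attr(ann, "chrom_lengths")

#' Read a genome annotation from GFF3 or TSV
#'
#' The TSV dialect is a 7-column tab-separated file with header
#' `gene_id chrom start end strand operon_id is_pseudo`, 1-based inclusive.
#' GFF3 gene features carry `ID`, `operon_id` and `is_pseudo` attributes.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return a [tn_annotation].
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_tn("annotation file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "tsv") {
    genes <- tryCatch(
      utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "")),
      error = function(e) stop_tn("failed to parse %s: %s", path, conditionMessage(e)))
    req <- c("gene_id", "chrom", "start", "end", "strand")
    miss <- setdiff(req, names(genes))
    if (length(miss))
      stop_tn("%s: missing column(s) %s (line 1)", path, paste(miss, collapse = ", "))
    bad <- which(is.na(genes$start) | is.na(genes$end))
    if (length(bad))
      stop_tn("%s: non-numeric coordinates at data line(s) %s",
              path, paste(bad + 1L, collapse = ", "))
    tn_annotation(genes)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[S4Vectors::mcols(gr)$type %in% c("gene", NA)]
    md <- S4Vectors::mcols(gr)
    genes <- data.frame(
      gene_id = as.character(md$ID),
      chrom = as.character(GenomeInfoDb::seqnames(gr)),
      start = BiocGenerics::start(gr),
      end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      operon_id = if ("operon_id" %in% names(md)) as.character(md$operon_id) else NA_character_,
      is_pseudo = if ("is_pseudo" %in% names(md)) as.logical(md$is_pseudo) else FALSE,
      stringsAsFactors = FALSE)
    sl <- GenomeInfoDb::seqlengths(gr)
    if (all(is.na(sl))) {   # fall back to parsing the pragmas directly
      pr <- grep("^##sequence-region", readLines(path), value = TRUE)
      if (length(pr)) {
        parts <- strsplit(trimws(pr), "\\s+")
        sl <- stats::setNames(vapply(parts, function(p) as.numeric(p[4]), 1),
                              vapply(parts, `[`, "", 2))
      }
    }
    cl <- if (all(is.na(sl))) NULL else { storage.mode(sl) <- "double"; sl }
    tn_annotation(genes, chrom_lengths = cl)
  }
}

#' Write a genome annotation to GFF3 or TSV
#'
#' @param ann a [tn_annotation].
#' @param path output file path.
#' @param format `"gff3"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(ann)[, c("gene_id", "chrom", "start", "end",
                                              "strand", "operon_id", "is_pseudo")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = ann$chrom,
      ranges = IRanges::IRanges(ann$start, ann$end),
      strand = ann$strand)
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- ann$gene_id
    S4Vectors::mcols(gr)$operon_id <- ann$operon_id
    S4Vectors::mcols(gr)$is_pseudo <- ann$is_pseudo
    cl <- chrom_lengths(ann)
    GenomeInfoDb::seqlengths(gr) <- cl[GenomeInfoDb::seqlevels(gr)]
    rtracklayer::export(gr, path, format = "gff3")
    # rtracklayer does not emit ##sequence-region pragmas; add them so that
    # chromosome bounds survive the round trip
    lines <- readLines(path)
    pragma <- sprintf("##sequence-region %s 1 %d", names(cl), as.integer(cl))
    writeLines(append(lines, pragma, after = 1L), path)
  }
  invisible(path)
}

#' Coding windows (5-85% rule) for every gene
#'
#' Only insertions between fractions `f_lo` and `f_hi` of a coding sequence,
#' measured 5'->3' on the coding strand, are considered disruptive. Offsets
#' `o` from the 5' end are kept when `floor(f_lo*L) <= o < floor(f_hi*L)`,
#' so `win_len = floor(f_hi*L) - floor(f_lo*L)` exactly.
#'
#' @param ann a [tn_annotation] (or any data.frame with gene coordinates).
#' @param f_lo,f_hi window fractions, `0 <= f_lo < f_hi <= 1`.
#' @return data.frame `gene_id`, `win_start`, `win_end`, `win_len`
#'   (1-based inclusive genomic coordinates).
#' @export
coding_window <- function(ann, f_lo = 0.05, f_hi = 0.85) {
  stopifnot(f_lo >= 0, f_hi <= 1, f_lo < f_hi)
  L <- ann$end - ann$start + 1L
  lo <- floor(f_lo * L)
  hi <- floor(f_hi * L)
  plus <- ann$strand == "+"
  win_start <- ifelse(plus, ann$start + lo, ann$end - hi + 1L)
  win_end <- ifelse(plus, ann$start + hi - 1L, ann$end - lo)
  data.frame(gene_id = ann$gene_id,
             win_start = as.integer(win_start),
             win_end = as.integer(win_end),
             win_len = as.integer(hi - lo),
             stringsAsFactors = FALSE)
}

#' Map genomic positions to genes or intergenic labels
#'
#' Positions inside one or more genes return the containing gene id(s),
#' comma-separated for overlapping genes. Intergenic positions are labelled
#' `"intergenic:<gene>:<bp>"` for the nearest gene whose 5' end lies
#' downstream of the position on that gene's strand (i.e. the position is
#' `<bp>` upstream of `<gene>`); when no such gene exists the nearest gene by
#' boundary distance is used instead.
#'
#' @param ann a [tn_annotation].
#' @param chrom chromosome name(s), recycled against `position`.
#' @param position 1-based bp position(s).
#' @return character vector of gene ids / intergenic labels.
#' @export
map_position <- function(ann, chrom, position) {
  n <- max(length(chrom), length(position))
  chrom <- rep_len(as.character(chrom), n)
  position <- rep_len(as.integer(position), n)
  cl <- chrom_lengths(ann)
  bad <- which(is.na(cl[chrom]) | position < 1L | position > cl[chrom])
  if (length(bad))
    stop_tn("position outside chromosome bounds at index %s",
            paste(bad, collapse = ", "))

  gr <- GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(ann$start, ann$end))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(position, position))
  ov <- GenomicRanges::findOverlaps(q, gr, ignore.strand = TRUE)
  hit_ids <- tapply(ann$gene_id[S4Vectors::subjectHits(ov)],
                    S4Vectors::queryHits(ov),
                    function(g) paste(sort(g), collapse = ","))
  out <- character(n)
  out[as.integer(names(hit_ids))] <- hit_ids

  inter <- which(out == "")
  if (length(inter)) {
    out[inter] <- vapply(inter, function(i) {
      on_chrom <- ann$chrom == chrom[i]
      p <- position[i]
      up_plus <- on_chrom & ann$strand == "+" & ann$start > p
      up_minus <- on_chrom & ann$strand == "-" & ann$end < p
      d <- rep(NA_real_, nrow(ann))
      d[up_plus] <- ann$start[up_plus] - p
      d[up_minus] <- p - ann$end[up_minus]
      if (all(is.na(d))) {          # no gene is downstream: fall back to nearest
        d <- pmax(ann$start - p, p - ann$end, 0)
        d[!on_chrom] <- NA_real_
      }
      j <- which.min(d)
      sprintf("intergenic:%s:%d", ann$gene_id[j], as.integer(d[j]))
    }, character(1))
  }
  out
}

#' @export
print.tn_annotation <- function(x, ...) {
  cat(sprintf("tn_annotation: %d genes on %d chromosome(s) (%s)\n",
              nrow(x), length(chrom_lengths(x)),
              paste(sprintf("%s=%d bp", names(chrom_lengths(x)),
                            as.integer(chrom_lengths(x))), collapse = ", ")))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more genes\n", nrow(x) - 6L))
  invisible(x)
}
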