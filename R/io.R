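#' Read a per-cytosine methylation call table
#'
#' Reads the tab-separated per-cytosine dialect used throughout the package:
#' one row per covered cytosine with header
#' `chrom, pos, strand, context, depth, meth_count`.  Positions are 0-based.
#' If a genome is supplied, the context of every call is re-derived from the
#' sequence and mismatches are rejected.
#'
#' @param path Path to a TSV file.
#' @param genome Optional [Biostrings::DNAStringSet] used to validate contexts.
#' @return A `data.frame` of validated calls (class `gm_calls`).
#' @export
read_methylation_table <- function(path, genome = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "integer", "character",
                                  "character", "integer", "integer"),
                   quote = "", comment.char = "")
  required <- c("chrom", "pos", "strand", "context", "depth", "meth_count")
  if (!identical(names(df)[seq_along(required)], required))
    stop("methylation table must have header: ", paste(required, collapse = ","))
  validate_calls(df, path = path)
  if (!is.null(genome)) {
    ctx <- derive_context(genome, df$chrom, df$pos, df$strand)
    bad <- which(ctx != df$context)
    if (length(bad))
      stop("context mismatch with genome at data line ", bad[1],
           ": table says ", df$context[bad[1]], ", genome says ", ctx[bad[1]])
  }
  class(df) <- c("gm_calls", "data.frame")
  df
}

validate_calls <- function(df, path = "<calls>") {
  bad <- which(is.na(df$depth) | is.na(df$meth_count) | is.na(df$pos))
  if (length(bad))
    stop("malformed row at data line ", bad[1], " of ", path)
  bad <- which(df$meth_count > df$depth | df$meth_count < 0 | df$depth < 0)
  if (length(bad))
    stop("meth_count/depth invalid at data line ", bad[1], " of ", path,
         " (meth_count must satisfy 0 <= meth_count <= depth)")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be + or - in ", path)
  if (!all(df$context %in% c("CG", "CHG", "CHH")))
    stop("context must be one of CG, CHG, CHH in ", path)
  if (anyDuplicated(paste(df$chrom, df$pos, df$strand)))
    stop("duplicate (chrom, pos, strand) in ", path)
  invisible(df)
}

#' Write a methylation call table
#'
#' @param calls A calls `data.frame` as returned by [read_methylation_table()].
#' @param path Output TSV path.
#' @export
write_methylation_table <- function(calls, path) {
  cols <- c("chrom", "pos", "strand", "context", "depth", "meth_count")
  write.table(calls[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Derive cytosine context (CG/CHG/CHH) from a genome
#'
#' For a plus-strand cytosine at 0-based position `pos` the context is read
#' from `pos, pos+1, pos+2`; for a minus-strand cytosine (a G on the plus
#' strand) it is read from the reverse complement of `pos-2, pos-1, pos`.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param chrom,pos,strand Parallel vectors locating each cytosine.
#' @return Character vector in `{CG, CHG, CHH}` (NA when off-chromosome or
#'   the base is not a cytosine on that strand).
#' @export
derive_context <- function(genome, chrom, pos, strand) {
  out <- rep(NA_character_, length(pos))
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  for (ch in unique(chrom)) {
    s <- as.character(genome[[ch]])
    idx <- which(chrom == ch)
    L <- lens[[ch]]
    p <- pos[idx]
    plus <- strand[idx] == "+"
    # plus strand: need bases at p, p+1, p+2 (1-based p+1..p+3)
    b1 <- substring(s, p + 1, p + 1)
    ok <- plus & b1 == "C"
    b2 <- ifelse(p + 2 <= L, substring(s, p + 2, p + 2), "N")
    b3 <- ifelse(p + 3 <= L, substring(s, p + 3, p + 3), "N")
    out[idx[ok & b2 == "G"]] <- "CG"
    out[idx[ok & b2 != "G" & b3 == "G"]] <- "CHG"
    out[idx[ok & b2 != "G" & b2 != "N" & b3 != "G" & b3 != "N"]] <- "CHH"
    # minus strand: C on minus = G on plus; read leftwards, complemented
    okm <- !plus & b1 == "G"
    m2 <- ifelse(p - 1 >= 0, substring(s, p, p), "N")
    m3 <- ifelse(p - 2 >= 0, substring(s, p - 1, p - 1), "N")
    out[idx[okm & m2 == "C"]] <- "CG"
    out[idx[okm & m2 != "C" & m3 == "C"]] <- "CHG"
    out[idx[okm & m2 != "C" & m2 != "N" & m3 != "C" & m3 != "N"]] <- "CHH"
  }
  out
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 coordinates (1-based closed) are converted to the package's 0-based
#' half-open convention; BED12 is read as-is.  The returned table has one row
#' per gene with exon structure as comma-separated 0-based half-open starts
#' and ends, and TSS/TTS as the first/last transcribed base (so `tss > tts`
#' in genomic coordinates for minus-strand genes).
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed12"`.
#' @return A `data.frame` with columns `gene_id, chrom, strand, start, end,
#'   tss, tts, exon_starts, exon_ends, cds_start, cds_end`.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gff3"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    genes <- gr[gr$type == "gene"]
    exons <- gr[gr$type == "exon"]
    cds <- gr[gr$type == "CDS"]
    ids <- as.character(genes$ID)
    if (anyDuplicated(ids)) stop("duplicate gene_id in ", path)
    parent <- function(x) vapply(as.list(x$Parent), `[`, "", 1L)
    ex_by <- split(seq_along(exons), parent(exons))
    cds_by <- split(seq_along(cds), parent(cds))
    rows <- lapply(seq_along(genes), function(i) {
      g <- genes[i]
      strand <- as.character(BiocGenerics::strand(g))
      if (!strand %in% c("+", "-")) stop("unknown strand for gene ", ids[i])
      gs <- BiocGenerics::start(g) - 1L; ge <- BiocGenerics::end(g)
      ei <- ex_by[[ids[i]]]
      if (is.null(ei)) { es <- gs; ee <- ge } else {
        es <- BiocGenerics::start(exons[ei]) - 1L
        ee <- BiocGenerics::end(exons[ei])
        o <- order(es); es <- es[o]; ee <- ee[o]
      }
      ci <- cds_by[[ids[i]]]
      cs <- if (is.null(ci)) NA_integer_ else min(BiocGenerics::start(cds[ci])) - 1L
      ce <- if (is.null(ci)) NA_integer_ else max(BiocGenerics::end(cds[ci]))
      data.frame(gene_id = ids[i], chrom = as.character(GenomicRanges::seqnames(g)),
                 strand = strand, start = gs, end = ge,
                 exon_starts = paste(es, collapse = ","),
                 exon_ends = paste(ee, collapse = ","),
                 cds_start = cs, cds_end = ce)
    })
    df <- do.call(rbind, rows)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (anyDuplicated(gr$name)) stop("duplicate gene_id in ", path)
    rows <- lapply(seq_along(gr), function(i) {
      g <- gr[i]
      strand <- as.character(BiocGenerics::strand(g))
      if (!strand %in% c("+", "-")) stop("unknown strand for gene ", g$name)
      gs <- BiocGenerics::start(g) - 1L; ge <- BiocGenerics::end(g)
      bl <- g$blocks[[1]]
      es <- gs + BiocGenerics::start(bl) - 1L
      ee <- gs + BiocGenerics::end(bl)
      data.frame(gene_id = g$name, chrom = as.character(GenomicRanges::seqnames(g)),
                 strand = strand, start = gs, end = ge,
                 exon_starts = paste(es, collapse = ","),
                 exon_ends = paste(ee, collapse = ","),
                 cds_start = if (!is.null(g$thick)) BiocGenerics::start(g$thick) - 1L else NA_integer_,
                 cds_end = if (!is.null(g$thick)) BiocGenerics::end(g$thick) else NA_integer_)
    })
    df <- do.call(rbind, rows)
  }
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df$tts <- ifelse(df$strand == "+", df$end - 1L, df$start)
  validate_gene_models(df)
  rownames(df) <- NULL
  df
}

validate_gene_models <- function(df) {
  for (i in seq_len(nrow(df))) {
    es <- exon_vec(df$exon_starts[i]); ee <- exon_vec(df$exon_ends[i])
    if (length(es) != length(ee) || any(es >= ee))
      stop("invalid exon intervals for gene ", df$gene_id[i])
    if (is.unsorted(es, strictly = TRUE) && length(es) > 1)
      stop("exons not sorted for gene ", df$gene_id[i])
    if (length(es) > 1 && any(es[-1] < ee[-length(ee)]))
      stop("overlapping exons for gene ", df$gene_id[i])
    if (min(es) < df$start[i] || max(ee) > df$end[i])
      stop("exon outside gene span for gene ", df$gene_id[i])
  }
  invisible(df)
}

exon_vec <- function(x) as.integer(strsplit(x, ",", fixed = TRUE)[[1]])

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_models()]: internal 0-based half-open coordinates
#' become 1-based closed GFF3 records (gene, exon, CDS).
#'
#' @param genes Gene-model `data.frame`.
#' @param path Output path.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    cat(sprintf("%s\tgoosemethyl\tgene\t%d\t%d\t.\t%s\t.\tID=%s\n",
                g$chrom, g$start + 1L, g$end, g$strand, g$gene_id), file = con)
    es <- exon_vec(g$exon_starts); ee <- exon_vec(g$exon_ends)
    for (j in seq_along(es))
      cat(sprintf("%s\tgoosemethyl\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s\n",
                  g$chrom, es[j] + 1L, ee[j], g$strand, g$gene_id, j, g$gene_id),
          file = con)
    if (!is.na(g$cds_start))
      cat(sprintf("%s\tgoosemethyl\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s\n",
                  g$chrom, g$cds_start + 1L, g$cds_end, g$strand, g$gene_id, g$gene_id),
          file = con)
  }
  invisible(path)
}

#' Write intervals as BED
#'
#' Scores in `[0, 1]` are scaled to the BED 0-1000 range; output is sorted by
#' chromosome then start.
#'
#' @param intervals `data.frame` with `chrom, start, end` (0-based half-open)
#'   and optionally `name` and `score` (in `[0,1]`).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0) {
    file.create(path)
    return(invisible(path))
  }
  if (any(intervals$start >= intervals$end))
    stop("BED intervals must have start < end")
  name <- if ("name" %in% names(intervals)) intervals$name
          else paste0("interval_", seq_len(nrow(intervals)))
  score <- if ("score" %in% names(intervals)) round(intervals$score * 1000)
           else rep(0L, nrow(intervals))
  df <- data.frame(chrom = intervals$chrom, start = intervals$start,
                   end = intervals$end, name = name, score = as.integer(score))
  df <- df[order(df$chrom, df$start), ]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file written by [write_bed()]
#'
#' @param path BED path.
#' @return `data.frame` with `chrom, start, end, name, score` (score rescaled
#'   back to `[0,1]`).
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric()))
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "numeric"))
  df$score <- df$score / 1000
  df
}

#' Read a sample sheet
#'
#' TSV with header `sample_id, breed, stage, replicate`.  Sample ids must be
#' unique; replicates must be positive integers.
#'
#' @param path TSV path.
#' @return Validated `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "character", "integer"))
  if (!identical(names(df), c("sample_id", "breed", "stage", "replicate")))
    stop("sample sheet must have header: sample_id, breed, stage, replicate")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  if (any(df$replicate < 1)) stop("replicate must be a positive integer")
  df
}

#' Check that every (breed, stage) group in a comparison has enough replicates
#' @param samples Sample sheet `data.frame`.
#' @param groups List of `(breed, stage)` pairs used in a comparison.
#' @param min_replicates Minimum group size for any test producing a p-value.
#' @export
check_group_replicates <- function(samples, groups, min_replicates = 2) {
  for (g in groups) {
    n <- sum(samples$breed == g[[1]] & samples$stage == g[[2]])
    if (n < min_replicates)
      stop("group (", g[[1]], ", ", g[[2]], ") has ", n,
           " replicates; at least ", min_replicates, " required")
  }
  invisible(TRUE)
}

#' Read an FPKM matrix
#'
#' TSV with a `gene_id` column followed by one column per sample.
#'
#' @param path TSV path.
#' @return Numeric matrix, genes in rows (rownames = gene ids).
#' @export
read_fpkm <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0)) stop("negative FPKM values")
  m
}

#' Write an FPKM matrix
#' @param fpkm Matrix as returned by [read_fpkm()].
#' @param path Output path.
#' @export
write_fpkm <- function(fpkm, path) {
  df <- data.frame(gene_id = rownames(fpkm), fpkm, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
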