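## Internal coordinate convention: 0-based, half-open [start, end).
## GFF3 I/O converts to/from the 1-based inclusive dialect at the boundary.

#' Create a stranded genomic interval
#'
#' Intervals are 0-based, half-open. Strand must be `"+"` or `"-"`;
#' unstranded features (e.g. peaks) store `"+"` by convention.
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must exceed `start`.
#' @param strand `"+"` or `"-"`.
#' @return A list of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("chrom must be a non-empty string")
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || end <= start)
    stop("interval requires 0 <= start < end (got [", start, ", ", end, "))")
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got '", strand, "'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

# canonicalize an exon matrix: 2 columns (start, end), sorted, validated disjoint
as_exon_matrix <- function(exons) {
  if (is.data.frame(exons)) exons <- as.matrix(exons[, c("start", "end")])
  if (is.vector(exons) && length(exons) == 2L) exons <- matrix(exons, ncol = 2L)
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("exon with end <= start")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("exons must be pairwise disjoint and sorted")
  exons
}

#' Create a transcript model (exon chain on a stranded chromosome)
#'
#' The unit of isoform classification: an ordered chain of disjoint exons,
#' optionally with 5'/3' UTR sub-intervals, on one strand of one chromosome.
#' Single-exon transcripts are valid and have an empty intron chain.
#'
#' @param transcript_id Transcript identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data frame of exon `start`, `end`
#'   (0-based half-open); rows need not be pre-sorted.
#' @param gene_id Gene identifier, or `NA` before locus assignment.
#' @param utr5,utr3 Optional UTR interval matrices in the same format.
#' @param source `"reference"` or `"isoseq"`.
#' @return A list of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons,
                             gene_id = NA_character_, utr5 = NULL, utr3 = NULL,
                             source = "reference") {
  if (!is.character(transcript_id) || !nzchar(transcript_id))
    stop("transcript_id must be a non-empty string")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-', got '", strand, "'")
  if (!source %in% c("reference", "isoseq")) stop("source must be 'reference' or 'isoseq'")
  exons <- as_exon_matrix(exons)
  if (any(exons < 0)) stop("negative exon coordinate")
  if (!is.null(utr5)) utr5 <- as_exon_matrix(utr5)
  if (!is.null(utr3)) utr3 <- as_exon_matrix(utr3)
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
    strand = strand, start = unname(exons[1L, 1L]),
    end = unname(exons[nrow(exons), 2L]),
    exons = exons, utr5 = utr5, utr3 = utr3, source = source
  ), class = "transcript_model")
}

#' Intron chain of a transcript
#'
#' @param model A `transcript_model`.
#' @return Two-column matrix (`start`, `end`) of the ordered gaps between
#'   consecutive exons; zero rows for single-exon transcripts.
#' @export
intron_chain <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2L) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = ex[-n, 2L], end = ex[-1L, 1L])
}

#' Exonic length (sum of exon sizes) of a transcript
#' @param model A `transcript_model`.
#' @return Number of exonic bases.
#' @export
exonic_length <- function(model) sum(model$exons[, 2L] - model$exons[, 1L])

# total overlap in bases between two sets of disjoint sorted intervals
interval_intersection_size <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1L], b[, 1L]); hi <- pmin(a[i, 2L], b[, 2L])
    tot <- tot + sum(pmax(0, hi - lo))
  }
  tot
}

# merge possibly-overlapping intervals into a disjoint sorted union
merge_intervals <- function(m) {
  if (nrow(m) <= 1L) return(m)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  out_s <- m[1L, 1L]; out_e <- m[1L, 2L]
  res <- list()
  for (i in 2L:nrow(m)) {
    if (m[i, 1L] <= out_e) {
      out_e <- max(out_e, m[i, 2L])
    } else {
      res[[length(res) + 1L]] <- c(out_s, out_e)
      out_s <- m[i, 1L]; out_e <- m[i, 2L]
    }
  }
  res[[length(res) + 1L]] <- c(out_s, out_e)
  matrix(unlist(res), ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("start", "end")))
}

#' Exonic overlap between two transcript models
#'
#' Shared exonic bases and the fractions of each model's exonic length they
#' represent. Models on different chromosomes or strands share zero bases.
#' `fraction_of_shorter` divides by the smaller exonic length and is the
#' quantity used by the "overlapped less than 20% of their length" rules.
#'
#' @param a,b `transcript_model` objects.
#' @return List with `shared_bases`, `fraction_of_a`, `fraction_of_b`,
#'   `fraction_of_shorter`.
#' @export
exonic_overlap <- function(a, b) {
  la <- exonic_length(a); lb <- exonic_length(b)
  shared <- if (identical(a$chrom, b$chrom) && identical(a$strand, b$strand))
    interval_intersection_size(a$exons, b$exons) else 0
  list(shared_bases = shared,
       fraction_of_a = shared / la,
       fraction_of_b = shared / lb,
       fraction_of_shorter = shared / min(la, lb))
}

#' Create a gene locus
#'
#' @param gene_id Gene identifier.
#' @param transcripts List of `transcript_model`s sharing one chromosome and
#'   strand.
#' @param status `"known"` or `"novel"`.
#' @return A list of class `gene_locus`; the span covers all transcripts.
#' @export
gene_locus <- function(gene_id, transcripts, status = "known") {
  if (!length(transcripts)) stop("a locus needs at least one transcript")
  if (!status %in% c("known", "novel")) stop("status must be 'known' or 'novel'")
  chrom <- transcripts[[1L]]$chrom; strand <- transcripts[[1L]]$strand
  for (tx in transcripts) {
    if (!identical(tx$chrom, chrom) || !identical(tx$strand, strand))
      stop("all transcripts of locus '", gene_id, "' must share chrom and strand")
  }
  transcripts <- lapply(transcripts, function(tx) { tx$gene_id <- gene_id; tx })
  # canonical order (start, then id) so construction, GFF3 output and
  # round-tripped input agree field-by-field
  transcripts <- transcripts[order(vapply(transcripts, `[[`, 0, "start"),
                                   vapply(transcripts, `[[`, "", "transcript_id"))]
  structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = min(vapply(transcripts, `[[`, 0, "start")),
    end = max(vapply(transcripts, `[[`, 0, "end")),
    transcripts = transcripts, status = status
  ), class = "gene_locus")
}

# natural chromosome ordering: chr1 < chr2 < chr10 < chrX
chrom_order <- function(chroms) {
  stripped <- sub("^chr", "", chroms)
  num <- suppressWarnings(as.numeric(stripped))
  order(is.na(num), num, stripped)
}

#' Create a genome annotation
#'
#' A collection of gene loci plus a chromosome registry with lengths. Loci
#' are stored in deterministic order (registry chromosome order, then start,
#' then gene id), which also fixes the byte output of [write_gff()].
#'
#' @param loci List of `gene_locus` objects.
#' @param chromosomes Optional named numeric vector of chromosome lengths;
#'   inferred from the loci (maximum end) when missing.
#' @return A list of class `genome_annotation` with elements `loci` (named by
#'   gene id) and `chromosomes`.
#' @export
genome_annotation <- function(loci, chromosomes = NULL) {
  gene_ids <- vapply(loci, `[[`, "", "gene_id")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_id in annotation")
  tx_ids <- unlist(lapply(loci, function(l)
    vapply(l$transcripts, `[[`, "", "transcript_id")))
  if (anyDuplicated(tx_ids)) stop("transcript ids must be globally unique")
  if (is.null(chromosomes)) {
    chroms <- unique(vapply(loci, `[[`, "", "chrom"))
    chroms <- chroms[chrom_order(chroms)]
    chromosomes <- vapply(chroms, function(cc)
      max(vapply(loci[vapply(loci, `[[`, "", "chrom") == cc], `[[`, 0, "end")),
      0)
  }
  bad <- setdiff(vapply(loci, `[[`, "", "chrom"), names(chromosomes))
  if (length(bad)) stop("chromosome not registered: ", paste(bad, collapse = ", "))
  ord <- order(match(vapply(loci, `[[`, "", "chrom"), names(chromosomes)),
               vapply(loci, `[[`, 0, "start"), gene_ids)
  loci <- loci[ord]
  names(loci) <- gene_ids[ord]
  structure(list(loci = loci, chromosomes = chromosomes),
            class = "genome_annotation")
}

#' Flat list of all transcripts in an annotation
#' @param annotation A `genome_annotation`.
#' @return Unnamed list of `transcript_model`s in locus order.
#' @export
annotation_transcripts <- function(annotation) {
  unlist(lapply(annotation$loci, `[[`, "transcripts"), recursive = FALSE,
         use.names = FALSE)
}

#' @export
print.genome_annotation <- function(x, ...) {
  n_tx <- sum(vapply(x$loci, function(l) length(l$transcripts), 0L))
  n_novel <- sum(vapply(x$loci, function(l) l$status == "novel", TRUE))
  cat("genome_annotation:", length(x$loci), "loci (", n_novel, "novel ),",
      n_tx, "transcripts on", length(x$chromosomes), "chromosomes\n")
  invisible(x)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s) %s:%d-%d(%s) %d exons\n",
              x$transcript_id, x$source, x$chrom, x$start, x$end, x$strand,
              nrow(x$exons)))
  invisible(x)
}

# intron chains as "chrom:strand:start-end" keys, the currency of junction
# support and reference-containment checks
intron_keys <- function(model) {
  ic <- intron_chain(model)
  if (!nrow(ic)) return(character(0))
  paste0(model$chrom, ":", model$strand, ":", ic[, 1L], "-", ic[, 2L])
}

# union of exons over all transcripts of a locus, merged
locus_exon_union <- function(locus) {
  merge_intervals(do.call(rbind, lapply(locus$transcripts, `[[`, "exons")))
}
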