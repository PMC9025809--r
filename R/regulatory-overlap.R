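## Peak/read feature-category annotation (promoter, UTRs, exon, intron,
## intergenic) and exact hypergeometric gene-set overlap testing.

FEATURE_CATEGORIES <- c("promoter", "five_prime_utr", "three_prime_utr",
                        "exon", "intron", "intergenic")

#' Create a ChIP-seq peak
#'
#' Peaks are strand-less; the stored strand is `"+"` by convention and
#' promoter orientation always comes from the gene.
#'
#' @param peak_id Peak identifier.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open coordinates.
#' @param counts Optional named per-sample counts for differential testing.
#' @return A list of class `peak`.
#' @export
peak <- function(peak_id, chrom, start, end, counts = NULL) {
  loc <- genomic_interval(chrom, start, end, "+")
  structure(list(peak_id = peak_id, chrom = chrom, start = loc$start,
                 end = loc$end, counts = counts), class = "peak")
}

# transcription start site as a point coordinate (strand-aware)
locus_tss <- function(locus) if (locus$strand == "+") locus$start else locus$end

promoter_window <- function(locus, upstream, downstream) {
  t0 <- locus_tss(locus)
  if (locus$strand == "+") c(t0 - upstream, t0 + downstream)
  else c(t0 - downstream, t0 + upstream)
}

# per-gene feature tables reused across subjects
build_feature_index <- function(annotation, promoter_upstream,
                                promoter_downstream) {
  lapply(annotation$loci, function(locus) {
    utr5 <- do.call(rbind, c(lapply(locus$transcripts, `[[`, "utr5"),
                             list(matrix(numeric(0), ncol = 2L))))
    utr3 <- do.call(rbind, c(lapply(locus$transcripts, `[[`, "utr3"),
                             list(matrix(numeric(0), ncol = 2L))))
    list(gene_id = locus$gene_id, chrom = locus$chrom,
         span = c(locus$start, locus$end), tss = locus_tss(locus),
         promoter = promoter_window(locus, promoter_upstream,
                                    promoter_downstream),
         utr5 = if (nrow(utr5)) merge_intervals(utr5) else utr5,
         utr3 = if (nrow(utr3)) merge_intervals(utr3) else utr3,
         exons = locus_exon_union(locus))
  })
}

point_in <- function(p, m) {
  nrow(m) > 0L && any(m[, 1L] <= p & p < m[, 2L])
}

classify_point <- function(p, chrom, index) {
  pick <- function(cands) {
    # ties: closest TSS, then lexicographic gene id
    d <- vapply(cands, function(g) abs(p - g$tss), 0)
    ids <- vapply(cands, `[[`, "", "gene_id")
    cands[[order(d, ids)[1L]]]$gene_id
  }
  on_chrom <- Filter(function(g) g$chrom == chrom, index)
  hits <- Filter(function(g) g$promoter[1L] <= p && p < g$promoter[2L], on_chrom)
  if (length(hits)) return(list(category = "promoter", gene_id = pick(hits)))
  hits <- Filter(function(g) point_in(p, g$utr5), on_chrom)
  if (length(hits)) return(list(category = "five_prime_utr", gene_id = pick(hits)))
  hits <- Filter(function(g) point_in(p, g$utr3), on_chrom)
  if (length(hits)) return(list(category = "three_prime_utr", gene_id = pick(hits)))
  hits <- Filter(function(g) point_in(p, g$exons), on_chrom)
  if (length(hits)) return(list(category = "exon", gene_id = pick(hits)))
  hits <- Filter(function(g) g$span[1L] <= p && p < g$span[2L], on_chrom)
  if (length(hits)) return(list(category = "intron", gene_id = pick(hits)))
  list(category = "intergenic", gene_id = NA_character_)
}

#' Annotate an interval with its genomic feature category
#'
#' The interval's midpoint is classified with priority promoter >
#' 5' UTR > 3' UTR > exon > intron > intergenic. The promoter window spans
#' `[TSS - promoter_upstream, TSS + promoter_downstream)` oriented by the
#' gene's strand; exon means inside the gene's exon union but outside its
#' UTR records; intron means inside the gene span but not exonic. The
#' assigned gene is the owner of the winning feature (ties: closest TSS,
#' then lexicographic gene id).
#'
#' @param subject A `genomic_interval`, `peak`, or list with `chrom`,
#'   `start`, `end`.
#' @param annotation A [genome_annotation()].
#' @param promoter_upstream,promoter_downstream Promoter window half-widths
#'   in bases (defaults 3000/3000).
#' @return List with `category` and `gene_id` (`NA` iff intergenic).
#' @export
annotate_feature <- function(subject, annotation, promoter_upstream = 3000,
                             promoter_downstream = 3000) {
  index <- build_feature_index(annotation, promoter_upstream,
                               promoter_downstream)
  classify_point(floor((subject$start + subject$end) / 2), subject$chrom, index)
}

#' Feature-category distribution of a set of intervals
#'
#' Every subject lands in exactly one of the six categories; counts sum to
#' the number of subjects and proportions to 1.
#'
#' @param subjects List of interval-like objects (`chrom`, `start`, `end`),
#'   or a data frame with those columns.
#' @param annotation A [genome_annotation()].
#' @param promoter_upstream,promoter_downstream Promoter window (bases).
#' @return Data frame with `category`, `count`, `proportion` over the six
#'   categories (zero rows included); attribute `"assignments"` carries the
#'   per-subject classification.
#' @export
feature_distribution <- function(subjects, annotation,
                                 promoter_upstream = 3000,
                                 promoter_downstream = 3000) {
  if (is.data.frame(subjects))
    subjects <- lapply(seq_len(nrow(subjects)), function(i)
      list(chrom = subjects$chrom[i], start = subjects$start[i],
           end = subjects$end[i]))
  index <- build_feature_index(annotation, promoter_upstream,
                               promoter_downstream)
  cats <- character(length(subjects))
  genes <- character(length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    cl <- classify_point(floor((s$start + s$end) / 2), s$chrom, index)
    cats[i] <- cl$category; genes[i] <- cl$gene_id
  }
  tab <- table(factor(cats, levels = FEATURE_CATEGORIES))
  out <- data.frame(category = FEATURE_CATEGORIES,
                    count = as.integer(tab),
                    proportion = if (length(subjects))
                      as.numeric(tab) / length(subjects) else rep(0, 6L),
                    stringsAsFactors = FALSE)
  attr(out, "assignments") <- data.frame(category = cats, gene_id = genes,
                                         stringsAsFactors = FALSE)
  out
}

#' Genes located in a set of peaks
#'
#' A gene is reported when any peak overlaps its span or its promoter window
#' by at least one base (set semantics).
#'
#' @param peaks List of [peak()]s or interval-like objects.
#' @param annotation A [genome_annotation()].
#' @param promoter_upstream,promoter_downstream Promoter window (bases).
#' @return Sorted character vector of gene ids.
#' @export
peaks_to_genes <- function(peaks, annotation, promoter_upstream = 3000,
                           promoter_downstream = 3000) {
  hits <- character(0)
  for (locus in annotation$loci) {
    win <- promoter_window(locus, promoter_upstream, promoter_downstream)
    lo <- min(locus$start, win[1L]); hi <- max(locus$end, win[2L])
    for (pk in peaks) {
      if (identical(pk$chrom, locus$chrom) && pk$start < hi && pk$end > lo) {
        hits <- c(hits, locus$gene_id)
        break
      }
    }
  }
  sort(unique(hits))
}

#' Exact hypergeometric gene-set overlap test
#'
#' Upper-tail probability that two gene sets drawn from a common universe
#' share at least the observed number of genes, plus the sample odds ratio of
#' the 2x2 membership table.
#'
#' @param set_a,set_b Character vectors of gene ids (duplicates ignored).
#' @param universe Number of genes in the universe; must be at least
#'   `|A union B|`.
#' @return List of class `overlap_test`: `overlap`, `size_a`, `size_b`,
#'   `universe`, `p_value`, `odds_ratio`.
#' @export
gene_overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- as.numeric(universe)
  if (universe < 1) stop("universe must be >= 1")
  if (universe < length(union(set_a, set_b)))
    stop("universe smaller than |A union B|")
  a <- length(intersect(set_a, set_b))
  sa <- length(set_a); sb <- length(set_b)
  p <- phyper(a - 1, sa, universe - sa, sb, lower.tail = FALSE)
  b <- sa - a; cc <- sb - a; d <- universe - sa - sb + a
  ad <- a * d; bc <- b * cc
  or <- if (bc == 0 && ad > 0) Inf else if (ad == 0 && bc > 0) 0 else
    if (ad == 0 && bc == 0) 1 else ad / bc
  structure(list(overlap = a, size_a = sa, size_b = sb, universe = universe,
                 p_value = p, odds_ratio = or), class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "overlap_test: %d of |A|=%d, |B|=%d in universe %g; p = %.4g, OR = %.3g\n",
    x$overlap, x$size_a, x$size_b, x$universe, x$p_value, x$odds_ratio))
  invisible(x)
}
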