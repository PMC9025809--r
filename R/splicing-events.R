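## Alternative-splicing event classification between isoform pairs of a
## locus. Five canonical types: exon skipping, intron retention,
## alternative 5'/3' splice sites, mutually exclusive exons. Events are
## called only inside the overlapping span of the two models, so transcript
## end differences are never reported as splicing events.

event_row <- function(type, chrom, start, end, strand, a_id, b_id) {
  data.frame(event_type = type, chrom = chrom, start = start, end = end,
             strand = strand, transcript_a = a_id, transcript_b = b_id,
             stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(event_type = character(0), chrom = character(0),
             start = numeric(0), end = numeric(0), strand = character(0),
             transcript_a = character(0), transcript_b = character(0),
             stringsAsFactors = FALSE)
}

#' Classify alternative-splicing events between two isoforms
#'
#' Compares the intron chains of two transcript models of the same locus
#' within their shared genomic span and reports canonical events:
#'
#' * `exon_skipping`: an intron of one model strictly contains a full exon of
#'   the other while both intron boundaries coincide with splice sites of
#'   that other model (one event per skipped exon).
#' * `intron_retention`: an exon of one model covers an intron of the other
#'   together with parts of both flanking exons; the variant region is the
#'   retained intron.
#' * `alt_5ss` / `alt_3ss`: two introns share exactly one boundary; the
#'   changed boundary is labelled 5' or 3' by transcription direction. Pairs
#'   whose differing region swallows a complete exon are left to the
#'   skipping/mutually-exclusive rules.
#' * `mutually_exclusive`: each model holds a distinct internal exon between
#'   a shared pair of outer splice sites.
#'
#' @param a,b `transcript_model`s on the same chromosome and strand.
#' @return Data frame with columns `event_type`, `chrom`, `start`, `end`,
#'   `strand`, `transcript_a`, `transcript_b`; zero rows when the models are
#'   structurally identical within the shared span.
#' @export
pairwise_events <- function(a, b) {
  if (!identical(a$chrom, b$chrom) || !identical(a$strand, b$strand))
    stop("pairwise_events requires models on the same chromosome and strand")
  lo <- max(a$start, b$start); hi <- min(a$end, b$end)
  if (lo >= hi) return(empty_events())
  strand <- a$strand; chrom <- a$chrom

  within_span <- function(m) m[m[, 1L] >= lo & m[, 2L] <= hi, , drop = FALSE]
  ia <- within_span(intron_chain(a)); ib <- within_span(intron_chain(b))
  sites_a <- unique(as.vector(intron_chain(a)))
  sites_b <- unique(as.vector(intron_chain(b)))
  out <- list()
  add <- function(type, s, e) out[[length(out) + 1L]] <<-
    event_row(type, chrom, s, e, strand, a$transcript_id, b$transcript_id)

  # exon skipping: intron of `host` contains full exon(s) of `other`,
  # flanking sites shared with `other`
  skip_scan <- function(host_introns, other_exons, other_sites) {
    hits <- list()
    for (k in seq_len(nrow(host_introns))) {
      d <- host_introns[k, 1L]; acc <- host_introns[k, 2L]
      if (!(d %in% other_sites && acc %in% other_sites)) next
      inside <- other_exons[other_exons[, 1L] > d & other_exons[, 2L] < acc,
                            , drop = FALSE]
      if (nrow(inside)) for (j in seq_len(nrow(inside)))
        hits[[length(hits) + 1L]] <- inside[j, ]
    }
    hits
  }
  for (h in skip_scan(ib, a$exons, sites_a)) add("exon_skipping", h[1L], h[2L])
  for (h in skip_scan(ia, b$exons, sites_b)) add("exon_skipping", h[1L], h[2L])

  # intron retention: exon of `other` covers intron of `host` plus flanks
  retention_scan <- function(host_introns, other_exons) {
    hits <- list()
    for (k in seq_len(nrow(host_introns))) {
      d <- host_introns[k, 1L]; acc <- host_introns[k, 2L]
      cover <- other_exons[other_exons[, 1L] < d & other_exons[, 2L] > acc,
                           , drop = FALSE]
      if (nrow(cover)) hits[[length(hits) + 1L]] <- c(d, acc)
    }
    hits
  }
  for (h in retention_scan(ia, b$exons)) add("intron_retention", h[1L], h[2L])
  for (h in retention_scan(ib, a$exons)) add("intron_retention", h[1L], h[2L])

  # alternative donor/acceptor: introns sharing exactly one boundary
  contains_full_exon <- function(s, e) {
    any(a$exons[, 1L] >= s & a$exons[, 2L] <= e) ||
      any(b$exons[, 1L] >= s & b$exons[, 2L] <= e)
  }
  if (nrow(ia) && nrow(ib)) {
    for (k in seq_len(nrow(ia))) for (l in seq_len(nrow(ib))) {
      s1 <- ia[k, 1L]; e1 <- ia[k, 2L]; s2 <- ib[l, 1L]; e2 <- ib[l, 2L]
      share_left <- s1 == s2; share_right <- e1 == e2
      if (share_left == share_right) next  # identical or unrelated
      if (share_left) {
        rs <- min(e1, e2); re <- max(e1, e2)
        changed_5prime <- strand == "-"  # right boundary is 5' on minus strand
      } else {
        rs <- min(s1, s2); re <- max(s1, s2)
        changed_5prime <- strand == "+"
      }
      if (contains_full_exon(rs, re)) next  # skipping / MXE territory
      add(if (changed_5prime) "alt_5ss" else "alt_3ss", rs, re)
    }
  }

  # mutually exclusive exons: distinct internal exons between shared outer
  # splice sites
  internal_exons <- function(m) {
    ex <- m$exons
    if (nrow(ex) < 3L) return(ex[0, , drop = FALSE])
    ex[-c(1L, nrow(ex)), , drop = FALSE]
  }
  flank_introns <- function(introns, ex) {
    left <- introns[introns[, 2L] == ex[1L], , drop = FALSE]
    right <- introns[introns[, 1L] == ex[2L], , drop = FALSE]
    if (nrow(left) != 1L || nrow(right) != 1L) return(NULL)
    c(left[1L, 1L], right[1L, 2L])
  }
  ea <- internal_exons(a); eb <- internal_exons(b)
  if (nrow(ea) && nrow(eb)) {
    for (k in seq_len(nrow(ea))) for (l in seq_len(nrow(eb))) {
      x1 <- ea[k, ]; x2 <- eb[l, ]
      if (x1[2L] > x2[1L] && x2[2L] > x1[1L]) next  # overlapping, not exclusive
      fa <- flank_introns(intron_chain(a), x1)
      fb <- flank_introns(intron_chain(b), x2)
      if (is.null(fa) || is.null(fb)) next
      if (fa[1L] == fb[1L] && fa[2L] == fb[2L])
        add("mutually_exclusive", min(x1[1L], x2[1L]), max(x1[2L], x2[2L]))
    }
  }

  if (!length(out)) return(empty_events())
  res <- do.call(rbind, out)
  res[!duplicated(res[c("event_type", "start", "end")]), , drop = FALSE]
}

#' Deduplicated alternative-splicing events of a locus
#'
#' Unions [pairwise_events()] over all unordered transcript pairs of the
#' locus; events with identical type and variant region are counted once,
#' matching the notion of a genome-wide event inventory. The retained
#' exemplar pair is the first in pair order.
#'
#' @param locus A [gene_locus()].
#' @return List with `events` (data frame, one exemplar row per distinct
#'   event) and `count`.
#' @export
locus_events <- function(locus) {
  txs <- locus$transcripts
  n <- length(txs)
  if (n < 2L) return(list(events = empty_events(), count = 0L))
  acc <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ev <- pairwise_events(txs[[i]], txs[[j]])
    if (nrow(ev)) acc[[length(acc) + 1L]] <- ev
  }
  if (!length(acc)) return(list(events = empty_events(), count = 0L))
  ev <- do.call(rbind, acc)
  ev <- ev[!duplicated(ev[c("event_type", "start", "end")]), , drop = FALSE]
  rownames(ev) <- NULL
  list(events = ev, count = nrow(ev))
}

#' Genome-wide alternative-splicing event inventory
#'
#' @param annotation A [genome_annotation()].
#' @return List with `events` (data frame including `gene_id`) and `count`
#'   (total over loci, deduplicated within each locus).
#' @export
annotation_events <- function(annotation) {
  acc <- list()
  for (locus in annotation$loci) {
    le <- locus_events(locus)
    if (le$count) {
      le$events$gene_id <- locus$gene_id
      acc[[length(acc) + 1L]] <- le$events
    }
  }
  if (!length(acc)) {
    ev <- empty_events(); ev$gene_id <- character(0)
    return(list(events = ev, count = 0L))
  }
  ev <- do.call(rbind, acc)
  rownames(ev) <- NULL
  list(events = ev, count = nrow(ev))
}
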