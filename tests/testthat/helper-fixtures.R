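# shared builders for compact fixtures

ex <- function(...) matrix(c(...), ncol = 2L, byrow = TRUE,
                           dimnames = list(NULL, c("start", "end")))

tx <- function(id, exons, strand = "+", chrom = "chr1", ...) {
  transcript_model(id, chrom, strand, exons, ...)
}

# one + strand gene with three exons, introns (200,300) and (400,500)
fixture_reference <- function() {
  t1 <- tx("TXA.1", ex(100, 200, 300, 400, 500, 600), gene_id = "GENEA")
  genome_annotation(list(gene_locus("GENEA", list(t1))),
                    chromosomes = c(chr1 = 10000))
}

# junction set supporting introns (200,300) and (700,800) on chr1 +
fixture_junctions <- function() {
  junction_set(data.frame(chrom = "chr1", start = c(200, 700),
                          end = c(300, 800), strand = "+",
                          stringsAsFactors = FALSE))
}

# twelve candidates with hand-derived retention outcomes against
# fixture_reference() + fixture_junctions():
#   intron (200,300): junction-supported and annotated
#   intron (400,500): annotated only; (700,800): supported only;
#   introns (210,310)/(410,510): neither
retention_fixture <- function() {
  spliced <- function(id, exons, count, pid)
    flnc_candidate(id, tx(id, exons, source = "isoseq"), count, pid)
  cands <- list(
    spliced("c01", ex(100, 210, 310, 400), 2, 90),      # C1 only
    spliced("c02", ex(100, 210, 310, 400), 1, 99.5),    # C2 only
    spliced("c03", ex(100, 210, 310, 400), 1, 98.5),    # dropped
    spliced("c04", ex(600, 700, 800, 900), 1, 95),      # C3 only
    spliced("c05", ex(100, 200, 300, 400, 500, 600), 1, 95), # C4 only
    spliced("c06", ex(100, 400), 1, 90),                # mono-exonic: C3+C4
    spliced("c07", ex(100, 200, 300, 400), 3, 99.9),    # C1+C3+C4
    spliced("c08", ex(100, 210, 310, 400), 1, 99),      # dropped (PID not > 99)
    spliced("c09", ex(100, 210, 310, 400), 2, 99.5),    # C1 only
    spliced("c10", ex(100, 200, 300, 410, 510, 600), 1, 90), # dropped (partial)
    spliced("c11", ex(300, 400, 500, 600), 1, 90),      # C4 only
    spliced("c12", ex(100, 210, 310, 400), 1, 99.001)   # C2 only
  )
  expected <- data.frame(
    candidate_id = sprintf("c%02d", 1:12),
    kept = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE,
             TRUE, TRUE),
    criteria = c("C1_multiread", "C2_single_read_high_pid", "",
                 "C3_junctions_supported", "C4_events_annotated",
                 "C3_junctions_supported,C4_events_annotated",
                 "C1_multiread,C3_junctions_supported,C4_events_annotated",
                 "", "C1_multiread", "", "C4_events_annotated",
                 "C2_single_read_high_pid"),
    stringsAsFactors = FALSE)
  list(candidates = cands, expected = expected)
}

# per-base brute-force exonic overlap for small transcripts
brute_exonic_overlap <- function(a, b) {
  if (!identical(a$chrom, b$chrom) || !identical(a$strand, b$strand)) return(0L)
  bases <- function(m) unlist(lapply(seq_len(nrow(m$exons)), function(i)
    seq(m$exons[i, 1L], m$exons[i, 2L] - 1L)))
  length(intersect(bases(a), bases(b)))
}

empty_junctions <- function() {
  junction_set(data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), strand = character(0),
                          stringsAsFactors = FALSE))
}
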