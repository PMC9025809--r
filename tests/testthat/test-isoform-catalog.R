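test_that("retention criteria follow the keep-if-any rule", {
  ref <- fixture_reference()
  jx <- fixture_junctions()
  # two FLNC reads suffice even with an unsupported, unannotated intron
  multi <- flnc_candidate("m", tx("m", ex(100, 210, 310, 400), source = "isoseq"),
                          2, 90)
  # one read below the PID bar with an unknown intron fails every criterion
  weak <- flnc_candidate("w", tx("w", ex(100, 210, 310, 400), source = "isoseq"),
                         1, 98.5)
  # one low-PID read rescued by full junction support
  supported <- flnc_candidate("s", tx("s", ex(100, 200, 300, 400),
                                      source = "isoseq"), 1, 95)
  res <- retain_candidates(list(multi, weak, supported), jx, ref)
  expect_equal(res$kept, c(TRUE, FALSE, TRUE))
  expect_equal(res$criteria[1], "C1_multiread")
  expect_match(res$criteria[3], "C3_junctions_supported")
  expect_error(retain_candidates(list(multi), jx, ref, pid_threshold = 101),
               "pid_threshold")
})

test_that("junction support is strand-specific", {
  ref <- fixture_reference()
  jx <- fixture_junctions()  # supports (200,300) on + only
  minus <- flnc_candidate("mn", tx("mn", ex(100, 200, 300, 400), strand = "-",
                                   source = "isoseq"), 1, 90)
  expect_false(retain_candidates(list(minus), jx, ref)$kept)
})

test_that("raising read count or PID never un-keeps a candidate", {
  ref <- fixture_reference()
  jx <- fixture_junctions()
  set.seed(71)
  for (i in 1:30) {
    n_ex <- sample(1:3, 1)
    starts <- sort(sample(seq(100, 2000, 10), n_ex))
    exm <- cbind(starts, starts + sample(50:90, n_ex, replace = TRUE))
    count <- sample(1:3, 1); pid <- runif(1, 90, 100)
    cand <- flnc_candidate("x", tx("x", merge_intervals(exm), source = "isoseq"),
                           count, pid)
    kept <- retain_candidates(list(cand), jx, ref)$kept
    bumped <- flnc_candidate("x", cand$model, count + 1, min(100, pid + 1))
    if (kept) expect_true(retain_candidates(list(bumped), jx, ref)$kept)
  }
})

test_that("collapse merges identical models, sums support and keeps <20% apart", {
  mk <- function(id, exons, count) flnc_candidate(id, tx(id, exons,
                                                         source = "isoseq"),
                                                  count, 99)
  # identical pair collapses with summed count
  res <- collapse_redundant(list(mk("a", ex(0, 100), 3), mk("b", ex(0, 100), 2)))
  expect_length(res$representatives, 1)
  expect_equal(res$representatives[[1]]$flnc_read_count, 5)
  expect_equal(res$representatives[[1]]$candidate_id, "a")

  # 10% of the shorter's bases: distinct isoforms
  res2 <- collapse_redundant(list(mk("a", ex(0, 100), 1), mk("b", ex(90, 200), 1)))
  expect_length(res2$representatives, 2)

  # opposite strands never link
  minus <- flnc_candidate("c", tx("c", ex(0, 100), strand = "-",
                                  source = "isoseq"), 1, 99)
  expect_length(collapse_redundant(list(mk("a", ex(0, 100), 1), minus))
                $representatives, 2)
})

test_that("single linkage chains a~b~c into one cluster and conserves support", {
  mk <- function(id, exons, count) flnc_candidate(id, tx(id, exons,
                                                         source = "isoseq"),
                                                  count, 99)
  a <- mk("a", ex(0, 100), 2)        # overlaps b 50%
  b <- mk("b", ex(50, 150), 1)       # overlaps a and c
  c <- mk("c", ex(100, 200), 4)      # disjoint from a
  expect_equal(exonic_overlap(a$model, c$model)$shared_bases, 0)
  res <- collapse_redundant(list(a, b, c))
  expect_length(res$representatives, 1)
  expect_equal(res$representatives[[1]]$candidate_id, "c")  # highest count
  expect_equal(res$representatives[[1]]$flnc_read_count, 7) # conserved total
  expect_equal(unique(res$membership$cluster), 1L)
})

test_that("collapse matches a brute-force transitive-closure oracle", {
  set.seed(93)
  for (rep in 1:10) {
    n <- 8
    cands <- lapply(seq_len(n), function(i) {
      s <- sample(seq(0, 600, 50), 1)
      flnc_candidate(paste0("r", i),
                     tx(paste0("r", i), ex(s, s + sample(60:200, 1)),
                        source = "isoseq"), sample(1:5, 1), 99)
    })
    link <- matrix(FALSE, n, n)
    for (i in 1:n) for (j in 1:n)
      link[i, j] <- i != j &&
        exonic_overlap(cands[[i]]$model, cands[[j]]$model)$fraction_of_shorter >= 0.2
    reach <- link | diag(n)
    for (k in 1:n) reach <- reach | (reach[, k] %o% reach[k, ] > 0)  # closure
    oracle_clusters <- apply(reach, 1L, function(r) min(which(r)))
    res <- collapse_redundant(cands)
    got <- res$membership$cluster
    expect_equal(length(unique(got)), length(unique(oracle_clusters)))
    expect_true(all(tapply(oracle_clusters, got, function(x)
      length(unique(x))) == 1))
  }
})

test_that("locus assignment takes the best-overlapping gene and seeds novel loci", {
  # two + strand genes; gene B shares fewer exonic bases with the probe
  ga <- gene_locus("GA", list(tx("ta", ex(0, 100, 200, 300))))
  gb <- gene_locus("GB", list(tx("tb", ex(600, 700))))
  ref <- genome_annotation(list(ga, gb), chromosomes = c(chr1 = 50000))
  probe <- flnc_candidate("p", tx("p", ex(250, 300, 600, 650),
                                  source = "isoseq"), 2, 99)
  # shares 50 bases with each gene; fraction_of_shorter ties at 0.5,
  # shared ties -> lexicographic gene id
  asg <- assign_loci(list(probe), ref)
  expect_equal(asg$assignments$gene_id, "GA")

  far <- flnc_candidate("f", tx("f", ex(20000, 20400), source = "isoseq"), 2, 99)
  asg2 <- assign_loci(list(far), ref)
  expect_true(asg2$assignments$novel_locus)
  expect_equal(asg2$assignments$gene_id, "NG.chr1.1")
  expect_equal(asg2$novel_loci[["NG.chr1.1"]]$status, "novel")

  # argmax beats a smaller qualifying overlap
  big <- gene_locus("GC", list(tx("tc", ex(1000, 1300))))
  ref3 <- genome_annotation(list(ga, big), chromosomes = c(chr1 = 50000))
  both <- flnc_candidate("q", tx("q", ex(250, 300, 1000, 1090),
                                 source = "isoseq"), 2, 99)
  # GA: 50/140 = 0.36; GC: 90/140 = 0.64
  expect_equal(assign_loci(list(both), ref3)$assignments$gene_id, "GC")
})

test_that("novel locus ids number leftmost starts per chromosome", {
  ref <- genome_annotation(list(
    gene_locus("G1", list(tx("t1", ex(0, 100))))),
    chromosomes = c(chr1 = 100000, chr2 = 100000))
  mk <- function(id, chrom, s) flnc_candidate(
    id, tx(id, ex(s, s + 200), chrom = chrom, source = "isoseq"), 2, 99)
  asg <- assign_loci(list(mk("x", "chr2", 50000), mk("y", "chr2", 1000),
                          mk("z", "chr1", 30000)), ref)
  got <- asg$assignments
  expect_equal(got$gene_id[got$candidate_id == "y"], "NG.chr2.1")
  expect_equal(got$gene_id[got$candidate_id == "x"], "NG.chr2.2")
  expect_equal(got$gene_id[got$candidate_id == "z"], "NG.chr1.1")
})

test_that("isoform status classification separates the novelty reasons", {
  t1 <- tx("t1", ex(100, 200, 300, 400, 500, 600))
  locus <- gene_locus("G", list(t1))
  # identical model: known
  same <- tx("s", ex(100, 200, 300, 400, 500, 600), source = "isoseq")
  expect_equal(classify_isoform_status(same, locus)$status, "known")
  # skipping the middle exon merges two introns into a new one
  skip <- tx("k", ex(100, 200, 500, 600), source = "isoseq")
  st <- classify_isoform_status(skip, locus)
  expect_equal(st$status, "novel")
  expect_equal(st$reason, "new_intron")
  # identical chain, 3' end shifted by 200: changed_3prime_end, not new_exon
  shifted <- tx("h", ex(100, 200, 300, 400, 500, 800), source = "isoseq")
  expect_equal(classify_isoform_status(shifted, locus)$reason,
               "changed_3prime_end")
  # a retained intron is an internal exonic region outside reference exons
  ir <- tx("r", ex(100, 400, 500, 600), source = "isoseq")
  expect_equal(classify_isoform_status(ir, locus)$reason, "new_exon")
  # within tolerance the 3' jitter keeps the isoform known
  jitter <- tx("j", ex(100, 200, 300, 400, 500, 640), source = "isoseq")
  expect_equal(classify_isoform_status(jitter, locus)$status, "known")
  # members of a novel locus are novel by that fact alone
  nl <- gene_locus("N", list(same), status = "novel")
  expect_equal(classify_isoform_status(same, nl)$reason, "novel_locus")
})

test_that("merge bookkeeping: 2 novel loci + 3 novel isoforms add 2 loci, 5 transcripts", {
  cfg <- sim_config(seed = 23, n_genes = 6, n_chromosomes = 1)
  ref <- simulate_reference_annotation(cfg)
  # one primary transcript from three distinct loci so the perturbed copies
  # cannot collapse with each other
  novel_in_known <- lapply(1:3, function(i) {
    src <- ref$loci[[i]]$transcripts[[
      which.max(vapply(ref$loci[[i]]$transcripts,
                       function(t) nrow(t$exons), 0L))]]
    m <- transcript_model(paste0("nv", i), src$chrom, src$strand,
                          src$exons[-2, , drop = FALSE], source = "isoseq")
    flnc_candidate(paste0("nv", i), m, 2, 100)
  })
  chr_end <- max(vapply(ref$loci, function(l) l$end, 0))
  novel_loci <- lapply(1:2, function(i) {
    s <- chr_end + 10000 * i
    flnc_candidate(paste0("nl", i),
                   tx(paste0("nl", i), ex(s, s + 500), source = "isoseq"),
                   2, 100)
  })
  up <- update_annotation(ref, c(novel_in_known, novel_loci), empty_junctions())
  n_tx <- function(a) sum(vapply(a$loci, function(l) length(l$transcripts), 0L))
  expect_equal(length(up$annotation$loci), length(ref$loci) + 2)
  expect_equal(n_tx(up$annotation), n_tx(ref) + 5)
  # novel transcript ids follow <chrom>.<locus>.<isoform> with chr stripped
  novel_ids <- unlist(lapply(up$annotation$loci, function(l)
    vapply(Filter(function(t) t$source == "isoseq", l$transcripts),
           `[[`, "", "transcript_id")))
  expect_true(all(grepl("^1\\.[0-9]+\\.[0-9]+$", novel_ids)))
})

test_that("merging no novel representatives returns the reference unchanged", {
  ref <- fixture_reference()
  out <- merge_annotation(ref, list(), list(),
                          data.frame(candidate_id = character(0),
                                     gene_id = character(0)))
  expect_equal(out, ref)
})

test_that("the updated annotation is idempotent under its own transcripts", {
  cfg <- sim_config(seed = 19, n_genes = 15, n_candidates = 50)
  ref <- simulate_reference_annotation(cfg)
  fl <- simulate_flnc_candidates(ref, cfg)
  jx <- simulate_junctions(ref, fl$candidates, cfg)
  up <- update_annotation(ref, fl$candidates, jx)
  reinject <- lapply(annotation_transcripts(up$annotation), function(t) {
    m <- transcript_model(paste0("RE_", t$transcript_id), t$chrom, t$strand,
                          t$exons, source = "isoseq")
    flnc_candidate(m$transcript_id, m, 2, 100)
  })
  up2 <- update_annotation(up$annotation, reinject, empty_junctions())
  expect_true(all(up2$decisions$status == "known", na.rm = TRUE))
  expect_equal(length(up2$annotation$loci), length(up$annotation$loci))
  n_tx <- function(a) sum(vapply(a$loci, function(l) length(l$transcripts), 0L))
  expect_equal(n_tx(up2$annotation), n_tx(up$annotation))
})
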