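# annotation with one + strand gene (TSS 10000) carrying UTRs, one - strand
# gene, and empty space beyond
overlap_reference <- function() {
  plus <- tx("tp", ex(10000, 10400, 12000, 12400, 14000, 14400),
             utr5 = ex(10000, 10100), utr3 = ex(14300, 14400))
  minus <- tx("tm", ex(40000, 40300, 42000, 42300), strand = "-")
  genome_annotation(list(gene_locus("GP", list(plus)),
                         gene_locus("GM", list(minus))),
                    chromosomes = c(chr1 = 200000))
}

test_that("midpoint classification follows the promoter-first priority", {
  ann <- overlap_reference()
  probe <- function(s, e) annotate_feature(list(chrom = "chr1", start = s,
                                                end = e), ann)
  # 500 bases upstream of the + strand TSS
  expect_equal(probe(9400, 9600),
               list(category = "promoter", gene_id = "GP"))
  # the 5' UTR itself sits inside the promoter window
  expect_equal(probe(10000, 10060)$category, "promoter")
  # past the window: exon, intron, 3' UTR
  expect_equal(probe(14100, 14200), list(category = "exon", gene_id = "GP"))
  expect_equal(probe(13198, 13202), list(category = "intron", gene_id = "GP"))
  expect_equal(probe(14320, 14380),
               list(category = "three_prime_utr", gene_id = "GP"))
  # the - strand gene's TSS is its right end
  expect_equal(probe(43000, 43100),
               list(category = "promoter", gene_id = "GM"))
  # 50 kb beyond everything
  expect_equal(probe(99000, 99100),
               list(category = "intergenic", gene_id = NA_character_))
})

test_that("shrinking the promoter window exposes the 5' UTR category", {
  ann <- overlap_reference()
  got <- annotate_feature(list(chrom = "chr1", start = 10000, end = 10060),
                          ann, promoter_upstream = 3000,
                          promoter_downstream = 0)
  expect_equal(got$category, "five_prime_utr")
})

test_that("feature_distribution partitions subjects and sums exactly", {
  ann <- overlap_reference()
  subjects <- c(
    replicate(3, list(chrom = "chr1", start = 9000, end = 9100), FALSE),
    replicate(2, list(chrom = "chr1", start = 13198, end = 13202), FALSE),
    replicate(5, list(chrom = "chr1", start = 99000, end = 99100), FALSE))
  fd <- feature_distribution(subjects, ann)
  expect_equal(fd$count[fd$category == "promoter"], 3L)
  expect_equal(fd$count[fd$category == "intron"], 2L)
  expect_equal(fd$count[fd$category == "intergenic"], 5L)
  expect_equal(sum(fd$count), 10L)
  expect_equal(sum(fd$proportion), 1, tolerance = 1e-9)
  empty <- feature_distribution(list(), ann)
  expect_equal(sum(empty$count), 0L)
})

test_that("enlarging the promoter window never demotes a promoter subject", {
  ann <- overlap_reference()
  set.seed(57)
  pts <- sample(8000:16000, 40)
  for (w in list(c(3000, 3000), c(5000, 5000))) {
    small <- vapply(pts, function(p) annotate_feature(
      list(chrom = "chr1", start = p, end = p + 1), ann, 2000, 2000)$category, "")
    big <- vapply(pts, function(p) annotate_feature(
      list(chrom = "chr1", start = p, end = p + 1), ann, w[1], w[2])$category, "")
    expect_true(all(big[small == "promoter"] == "promoter"))
  }
})

test_that("peaks_to_genes uses 1-base overlap with span or promoter", {
  ann <- overlap_reference()
  expect_equal(peaks_to_genes(list(), ann), character(0))
  # peak bridging the gap upstream of GP touches only its promoter
  expect_equal(peaks_to_genes(list(peak("p1", "chr1", 6990, 7100)), ann), "GP")
  # wholly intergenic beyond every window
  expect_equal(peaks_to_genes(list(peak("p2", "chr1", 99000, 99200)), ann),
               character(0))
  # one peak spanning two genes reports both
  wide <- peak("p3", "chr1", 14300, 40100)
  expect_equal(peaks_to_genes(list(wide), ann), c("GM", "GP"))
})

test_that("gene_overlap_test matches enumerated hypergeometric tails", {
  # disjoint sets: P(X >= 0) = 1
  d <- gene_overlap_test(c("a", "b"), c("c", "d"), 20)
  expect_equal(d$p_value, 1)
  expect_equal(d$overlap, 0)

  # universe 20, |A| = 5, |B| = 4, overlap 3, enumerated directly
  u <- paste0("g", 1:20)
  A <- u[1:5]; B <- c(u[1:3], u[10])
  got <- gene_overlap_test(A, B, 20)
  manual <- sum(choose(5, 3:4) * choose(15, 4 - (3:4))) / choose(20, 4)
  expect_equal(got$p_value, manual, tolerance = 1e-12)
  expect_equal(got$overlap, 3)
  expect_equal(got$odds_ratio, (3 * 14) / (2 * 1))

  # degenerate table: A = B = universe
  full <- gene_overlap_test(u, u, 20)
  expect_equal(full$p_value, 1)
  expect_equal(full$odds_ratio, 1)

  expect_error(gene_overlap_test(u[1:5], u[6:10], 8), "universe smaller")
})

test_that("overlap p-value is monotone non-increasing in the overlap", {
  u <- paste0("g", 1:30)
  ps <- vapply(0:6, function(k) {
    B <- c(u[seq_len(k)], u[10 + seq_len(6 - k)])  # |B| = 6, overlap = k
    gene_overlap_test(u[1:10], B, 30)$p_value
  }, 0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("odds ratio edge cases follow the 2x2 conventions", {
  u <- paste0("g", 1:10)
  # b*c = 0 with a*d > 0: A inside B
  inside <- gene_overlap_test(u[1:3], u[1:5], 10)
  expect_equal(inside$odds_ratio, Inf)
  # a = 0 with b*c > 0
  apart <- gene_overlap_test(u[1:3], u[4:6], 10)
  expect_equal(apart$odds_ratio, 0)
})
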