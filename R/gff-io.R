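## GFF3 and BED readers/writers. GFF3 is 1-based inclusive on disk and
## 0-based half-open in memory; BED is already 0-based half-open.

parse_gff_attributes <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(parts)]
  kv <- regmatches(parts, regexpr("=", parts, fixed = TRUE), invert = TRUE)
  vals <- vapply(kv, function(p) if (length(p) == 2L) p[2L] else "", "")
  names(vals) <- vapply(kv, `[[`, "", 1L)
  vals
}

#' Read a GFF3 genome annotation
#'
#' Parses `gene`, `mRNA`/`transcript`, `exon`, `five_prime_UTR` and
#' `three_prime_UTR` records linked by `ID`/`Parent` attributes. Coordinates
#' are converted from the 1-based inclusive GFF3 dialect to the internal
#' 0-based half-open convention. `##sequence-region` directives populate the
#' chromosome registry. Strand `"."` is rejected: every downstream rule is
#' strand-conditional.
#'
#' @param path Path to a GFF3 file.
#' @return A [genome_annotation()].
#' @export
read_gff <- function(path) {
  lines <- readLines(path)
  chroms <- numeric(0)
  genes <- list(); txs <- list(); tx_exons <- list()
  tx_utr5 <- list(); tx_utr3 <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      if (startsWith(line, "##sequence-region")) {
        f <- strsplit(trimws(line), "[ \t]+")[[1L]]
        if (length(f) >= 4L) chroms[f[2L]] <- as.numeric(f[4L])
      }
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L)
      stop("GFF3 parse error at line ", i, ": expected 9 fields, got ", length(f))
    type <- f[3L]
    if (!type %in% c("gene", "mRNA", "transcript", "exon",
                     "five_prime_UTR", "three_prime_UTR")) next
    start1 <- suppressWarnings(as.numeric(f[4L]))
    end1 <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(start1) || is.na(end1) || end1 < start1)
      stop("GFF3 parse error at line ", i, ": malformed coordinates (end < start?)")
    strand <- f[7L]
    if (!strand %in% c("+", "-"))
      stop("GFF3 parse error at line ", i, ": unknown strand symbol '", strand, "'")
    at <- parse_gff_attributes(f[9L])
    rec <- list(chrom = f[1L], start = start1 - 1, end = end1, strand = strand,
                id = unname(at["ID"]), parent = unname(at["Parent"]),
                attrs = at, line = i)
    if (type == "gene") {
      if (is.na(rec$id)) stop("GFF3 parse error at line ", i, ": gene without ID")
      genes[[rec$id]] <- rec
    } else if (type %in% c("mRNA", "transcript")) {
      if (is.na(rec$id)) stop("GFF3 parse error at line ", i, ": transcript without ID")
      if (is.na(rec$parent))
        stop("GFF3 parse error at line ", i, ": transcript without Parent")
      txs[[rec$id]] <- rec
    } else {
      if (is.na(rec$parent))
        stop("GFF3 parse error at line ", i, ": ", type, " without Parent")
      slot <- switch(type, exon = "exon", five_prime_UTR = "utr5",
                     three_prime_UTR = "utr3")
      key <- rec$parent
      ent <- c(rec$start, rec$end)
      if (slot == "exon") tx_exons[[key]] <- rbind(tx_exons[[key]], ent)
      else if (slot == "utr5") tx_utr5[[key]] <- rbind(tx_utr5[[key]], ent)
      else tx_utr3[[key]] <- rbind(tx_utr3[[key]], ent)
    }
  }
  orphans <- setdiff(names(tx_exons), names(txs))
  if (length(orphans))
    stop("GFF3 parse error: exon without resolvable parent transcript: ",
         paste(orphans, collapse = ", "))
  loci <- list()
  by_gene <- if (length(txs))
    split(names(txs), vapply(txs, `[[`, "", "parent")) else list()
  missing_genes <- setdiff(names(by_gene), names(genes))
  if (length(missing_genes))
    stop("GFF3 parse error: transcript with unresolvable gene Parent: ",
         paste(missing_genes, collapse = ", "))
  for (gid in names(genes)) {
    tids <- by_gene[[gid]]
    if (is.null(tids)) stop("GFF3 parse error: gene '", gid, "' has no transcripts")
    models <- lapply(tids, function(tid) {
      r <- txs[[tid]]
      ex <- tx_exons[[tid]]
      if (is.null(ex))
        stop("GFF3 parse error: transcript '", tid, "' has no exons")
      src <- r$attrs["model_source"]
      transcript_model(tid, r$chrom, r$strand, ex, gene_id = gid,
                       utr5 = tx_utr5[[tid]], utr3 = tx_utr3[[tid]],
                       source = if (!is.na(src)) unname(src) else "reference")
    })
    st <- genes[[gid]]$attrs["status"]
    loci[[gid]] <- gene_locus(gid, models,
                              status = if (!is.na(st)) unname(st) else "known")
  }
  genome_annotation(loci, chromosomes = if (length(chroms)) chroms else NULL)
}

fmt_gff_row <- function(chrom, type, start0, end0, strand, attrs) {
  paste(chrom, "oviso", type, format(start0 + 1, scientific = FALSE, trim = TRUE),
        format(end0, scientific = FALSE, trim = TRUE), ".", strand, ".",
        attrs, sep = "\t")
}

#' Write a genome annotation as GFF3
#'
#' Emits 1-based inclusive records ordered by chromosome registry order, then
#' start, then the gene/mRNA/exon/UTR hierarchy. Byte output is deterministic
#' for a fixed annotation, and `read_gff(write_gff(a))` reproduces `a`
#' field-by-field.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(annotation, path) {
  out <- c("##gff-version 3")
  for (cc in names(annotation$chromosomes)) {
    out <- c(out, paste("##sequence-region", cc, 1,
                        format(annotation$chromosomes[[cc]],
                               scientific = FALSE, trim = TRUE)))
  }
  for (locus in annotation$loci) {
    gat <- paste0("ID=", locus$gene_id)
    if (locus$status != "known") gat <- paste0(gat, ";status=", locus$status)
    out <- c(out, fmt_gff_row(locus$chrom, "gene", locus$start, locus$end,
                              locus$strand, gat))
    tx_ord <- order(vapply(locus$transcripts, `[[`, 0, "start"),
                    vapply(locus$transcripts, `[[`, "", "transcript_id"))
    for (tx in locus$transcripts[tx_ord]) {
      tat <- paste0("ID=", tx$transcript_id, ";Parent=", locus$gene_id)
      if (tx$source != "reference") tat <- paste0(tat, ";model_source=", tx$source)
      out <- c(out, fmt_gff_row(tx$chrom, "mRNA", tx$start, tx$end, tx$strand, tat))
      pat <- paste0("Parent=", tx$transcript_id)
      for (i in seq_len(nrow(tx$exons)))
        out <- c(out, fmt_gff_row(tx$chrom, "exon", tx$exons[i, 1L],
                                  tx$exons[i, 2L], tx$strand, pat))
      for (slot in c("utr5", "utr3")) {
        m <- tx[[slot]]
        if (is.null(m)) next
        type <- if (slot == "utr5") "five_prime_UTR" else "three_prime_UTR"
        for (i in seq_len(nrow(m)))
          out <- c(out, fmt_gff_row(tx$chrom, type, m[i, 1L], m[i, 2L],
                                    tx$strand, pat))
      }
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Read spliced alignments from a BED12 file
#'
#' Block starts/sizes are expanded into exon chains; adjacent or overlapping
#' blocks are merged so the result satisfies the transcript-model invariants.
#'
#' @param path Path to a BED12 file.
#' @param source Stored on each model; defaults to `"isoseq"`.
#' @return List of `transcript_model`s named by the BED `name` column.
#' @export
read_bed12 <- function(path, source = "isoseq") {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 12L) stop("BED12 requires 12 columns, got ", ncol(df))
  models <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    start <- as.numeric(df[i, 2L])
    sizes <- as.numeric(strsplit(as.character(df[i, 11L]), ",")[[1L]])
    offs <- as.numeric(strsplit(as.character(df[i, 12L]), ",")[[1L]])
    if (length(sizes) != length(offs) || length(sizes) != as.integer(df[i, 10L]))
      stop("BED12 block count mismatch for record '", df[i, 4L], "'")
    ex <- merge_intervals(cbind(start + offs, start + offs + sizes))
    models[[i]] <- transcript_model(as.character(df[i, 4L]),
                                    as.character(df[i, 1L]),
                                    as.character(df[i, 6L]), ex,
                                    source = source)
  }
  names(models) <- vapply(models, `[[`, "", "transcript_id")
  models
}

#' Write transcript models as BED12
#' @param models List of `transcript_model`s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(models, path) {
  rows <- vapply(models, function(m) {
    ex <- m$exons
    paste(m$chrom,
          format(m$start, scientific = FALSE, trim = TRUE),
          format(m$end, scientific = FALSE, trim = TRUE),
          m$transcript_id, 0, m$strand,
          format(m$start, scientific = FALSE, trim = TRUE),
          format(m$end, scientific = FALSE, trim = TRUE), "0,0,0", nrow(ex),
          paste(format(ex[, 2L] - ex[, 1L], scientific = FALSE, trim = TRUE),
                collapse = ","),
          paste(format(ex[, 1L] - m$start, scientific = FALSE, trim = TRUE),
                collapse = ","),
          sep = "\t")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(rows, con, sep = "\n")
  invisible(path)
}

#' Read an intron (splice-junction) set from 6-column BED
#'
#' Each record is one intron: `start` is the donor-side boundary and `end`
#' the acceptor-side boundary in 0-based half-open coordinates (strand
#' decides which end is the biological donor).
#'
#' @param path Path to a BED6 file.
#' @return A `junction_set` data frame with columns `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_junctions_bed <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("junction BED requires 6 columns")
  junction_set(data.frame(chrom = as.character(df[[1L]]),
                          start = as.numeric(df[[2L]]),
                          end = as.numeric(df[[3L]]),
                          strand = as.character(df[[6L]]),
                          stringsAsFactors = FALSE))
}

#' Write a junction set as 6-column BED
#' @param junctions A `junction_set` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_junctions_bed <- function(junctions, path) {
  rows <- paste(junctions$chrom,
                format(junctions$start, scientific = FALSE, trim = TRUE),
                format(junctions$end, scientific = FALSE, trim = TRUE),
                paste0("J", seq_len(nrow(junctions))), 0, junctions$strand,
                sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(rows, con, sep = "\n")
  invisible(path)
}
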