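## FLNC isoform candidate retention, redundancy collapse, locus assignment,
## known/novel classification and annotation merging.

#' Create an FLNC isoform candidate
#'
#' A transcript model plus its full-length non-concatemer (FLNC) read support
#' and alignment percent identity (PID), the two quantities the retention
#' criteria consume.
#'
#' @param candidate_id Candidate identifier.
#' @param model A `transcript_model` for the spliced alignment.
#' @param flnc_read_count Number of FLNC reads supporting the candidate
#'   (>= 1).
#' @param percent_identity Alignment identity in `[0, 100]`.
#' @return A list of class `flnc_candidate`.
#' @export
flnc_candidate <- function(candidate_id, model, flnc_read_count,
                           percent_identity) {
  if (!inherits(model, "transcript_model")) stop("model must be a transcript_model")
  flnc_read_count <- as.numeric(flnc_read_count)
  percent_identity <- as.numeric(percent_identity)
  if (is.na(flnc_read_count) || flnc_read_count < 1)
    stop("flnc_read_count must be >= 1")
  if (is.na(percent_identity) || percent_identity < 0 || percent_identity > 100)
    stop("percent_identity must lie in [0, 100]")
  structure(list(candidate_id = candidate_id, model = model,
                 flnc_read_count = flnc_read_count,
                 percent_identity = percent_identity),
            class = "flnc_candidate")
}

#' Create a junction set
#'
#' The set of short-read-supported introns, each identified by chromosome,
#' strand and donor/acceptor boundaries in 0-based half-open coordinates.
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `strand`.
#' @return The validated data frame with class `junction_set`.
#' @export
junction_set <- function(df) {
  need <- c("chrom", "start", "end", "strand")
  if (!all(need %in% names(df))) stop("junction_set needs columns ",
                                      paste(need, collapse = ", "))
  if (any(df$end <= df$start)) stop("junction with acceptor <= donor boundary")
  if (!all(df$strand %in% c("+", "-"))) stop("junction strand must be '+' or '-'")
  df <- unique(df[need])
  class(df) <- c("junction_set", "data.frame")
  df
}

junction_set_keys <- function(junctions) {
  paste0(junctions$chrom, ":", junctions$strand, ":",
         junctions$start, "-", junctions$end)
}

# all intron keys present anywhere in a reference annotation
reference_intron_universe <- function(reference) {
  unique(unlist(lapply(annotation_transcripts(reference), intron_keys)))
}

#' Evaluate the four FLNC retention criteria
#'
#' A candidate is kept when it meets at least one criterion:
#' `C1_multiread` -- supported by at least two FLNC reads;
#' `C2_single_read_high_pid` -- a single read with PID above
#' `pid_threshold`; `C3_junctions_supported` -- every intron present in the
#' short-read junction set (single-exon candidates satisfy this vacuously);
#' `C4_events_annotated` -- every intron present in the reference
#' annotation's intron universe (the computable junction-level reading of
#' "all splicing events already annotated").
#'
#' @param candidates List of [flnc_candidate()] objects.
#' @param junctions A [junction_set()].
#' @param reference Reference [genome_annotation()].
#' @param pid_threshold PID cutoff for the single-read criterion (default 99;
#'   the criterion is strict: PID must exceed it).
#' @return Data frame with one row per candidate: `candidate_id`, `kept`,
#'   `criteria` (comma-separated criterion labels, empty when dropped).
#' @export
retain_candidates <- function(candidates, junctions, reference,
                              pid_threshold = 99) {
  if (pid_threshold < 0 || pid_threshold > 100)
    stop("pid_threshold must lie in [0, 100]")
  jkeys <- junction_set_keys(junctions)
  universe <- reference_intron_universe(reference)
  rows <- lapply(candidates, function(cand) {
    ik <- intron_keys(cand$model)
    met <- c(
      C1_multiread = cand$flnc_read_count >= 2,
      C2_single_read_high_pid = cand$flnc_read_count == 1 &&
        cand$percent_identity > pid_threshold,
      C3_junctions_supported = all(ik %in% jkeys),
      C4_events_annotated = all(ik %in% universe)
    )
    data.frame(candidate_id = cand$candidate_id, kept = any(met),
               criteria = paste(names(met)[met], collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# union-find single linkage on candidate models using fraction_of_shorter
link_clusters_by_overlap <- function(models, min_fraction = 0.2) {
  n <- length(models)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    chroms <- vapply(models, `[[`, "", "chrom")
    strands <- vapply(models, `[[`, "", "strand")
    starts <- vapply(models, `[[`, 0, "start")
    ends <- vapply(models, `[[`, 0, "end")
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (chroms[i] != chroms[j] || strands[i] != strands[j]) next
      if (ends[i] <= starts[j] || ends[j] <= starts[i]) next
      ov <- exonic_overlap(models[[i]], models[[j]])
      if (ov$fraction_of_shorter >= min_fraction) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  vapply(seq_len(n), find, 0L)
}

#' Collapse redundant isoform candidates
#'
#' Single-linkage clustering of retained candidates: two candidates link when
#' they lie on the same strand and share at least `min_fraction` (default
#' 20%) of the shorter candidate's exonic length; candidates overlapping less
#' than that are distinct isoforms. Each cluster is represented by the
#' candidate with the highest FLNC read count (ties: larger exonic length,
#' then lexicographically smallest id); the representative's read count
#' becomes the cluster total.
#'
#' @param candidates List of retained [flnc_candidate()]s.
#' @param min_fraction Linking threshold on `fraction_of_shorter`.
#' @return List with `representatives` (list of `flnc_candidate`) and
#'   `membership` (data frame `candidate_id`, `representative_id`, `cluster`).
#' @export
collapse_redundant <- function(candidates, min_fraction = 0.2) {
  if (!length(candidates))
    return(list(representatives = list(),
                membership = data.frame(candidate_id = character(0),
                                        representative_id = character(0),
                                        cluster = integer(0))))
  models <- lapply(candidates, `[[`, "model")
  cl <- link_clusters_by_overlap(models, min_fraction)
  ids <- vapply(candidates, `[[`, "", "candidate_id")
  counts <- vapply(candidates, `[[`, 0, "flnc_read_count")
  exlens <- vapply(models, exonic_length, 0)
  reps <- list()
  membership <- data.frame(candidate_id = ids,
                           representative_id = NA_character_,
                           cluster = match(cl, sort(unique(cl))),
                           stringsAsFactors = FALSE)
  for (k in sort(unique(cl))) {
    idx <- which(cl == k)
    ord <- idx[order(-counts[idx], -exlens[idx], ids[idx])]
    rep_i <- ord[1L]
    rep_cand <- candidates[[rep_i]]
    rep_cand$flnc_read_count <- sum(counts[idx])
    reps[[length(reps) + 1L]] <- rep_cand
    membership$representative_id[idx] <- ids[rep_i]
  }
  list(representatives = reps, membership = membership)
}

#' Assign collapsed representatives to gene loci
#'
#' A representative joins the known gene whose exon union shares the largest
#' `fraction_of_shorter` with it, provided that fraction reaches
#' `min_fraction` (ties: more shared bases, then lexicographic gene id).
#' Representatives matching no known gene are clustered among themselves by
#' the same rule into novel loci with ids `NG.<chrom>.<k>`, `k` numbering
#' leftmost starts per chromosome.
#'
#' @param representatives List of [flnc_candidate()]s (post-collapse).
#' @param reference Reference [genome_annotation()].
#' @param min_fraction Overlap threshold (default 0.2).
#' @return List with `assignments` (data frame `candidate_id`, `gene_id`,
#'   `novel_locus`) and `novel_loci` (list of `gene_locus` shells holding the
#'   assigned representatives' models).
#' @export
assign_loci <- function(representatives, reference, min_fraction = 0.2) {
  gene_union <- lapply(reference$loci, locus_exon_union)
  gene_len <- vapply(gene_union, function(m) sum(m[, 2L] - m[, 1L]), 0)
  gene_chrom <- vapply(reference$loci, `[[`, "", "chrom")
  gene_strand <- vapply(reference$loci, `[[`, "", "strand")
  gene_ids <- names(reference$loci)

  n <- length(representatives)
  assigned <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    m <- representatives[[i]]$model
    mlen <- exonic_length(m)
    cand_genes <- which(gene_chrom == m$chrom & gene_strand == m$strand)
    best <- NULL
    for (g in cand_genes) {
      shared <- interval_intersection_size(m$exons, gene_union[[g]])
      if (shared <= 0) next
      frac <- shared / min(mlen, gene_len[g])
      if (frac < min_fraction) next
      rec <- list(frac = frac, shared = shared, gid = gene_ids[g])
      if (is.null(best) || rec$frac > best$frac ||
          (rec$frac == best$frac && (rec$shared > best$shared ||
           (rec$shared == best$shared && rec$gid < best$gid))))
        best <- rec
    }
    if (!is.null(best)) assigned[i] <- best$gid
  }

  ids <- vapply(representatives, function(x) x$candidate_id, "")
  assignments <- data.frame(candidate_id = ids, gene_id = assigned,
                            novel_locus = is.na(assigned),
                            stringsAsFactors = FALSE)

  novel_loci <- list()
  un <- which(is.na(assigned))
  if (length(un)) {
    models <- lapply(representatives[un], `[[`, "model")
    cl <- link_clusters_by_overlap(models, min_fraction)
    # number clusters by leftmost start within each chromosome
    cl_chrom <- vapply(split(seq_along(un), cl), function(ix)
      models[[ix[1L]]]$chrom, "")
    cl_start <- vapply(split(seq_along(un), cl), function(ix)
      min(vapply(models[ix], `[[`, 0, "start")), 0)
    cl_ids <- names(cl_chrom)
    new_gids <- rep(NA_character_, length(cl_ids))
    for (cc in unique(cl_chrom)) {
      here <- which(cl_chrom == cc)
      ord <- here[order(cl_start[here])]
      new_gids[ord] <- paste0("NG.", cc, ".", seq_along(ord))
    }
    names(new_gids) <- cl_ids
    for (k in seq_along(cl_ids)) {
      ix <- un[cl == as.integer(cl_ids[k])]
      gid <- new_gids[[cl_ids[k]]]
      assignments$gene_id[ix] <- gid
      novel_loci[[gid]] <- gene_locus(
        gid, lapply(representatives[ix], `[[`, "model"), status = "novel")
    }
  }
  list(assignments = assignments, novel_loci = novel_loci)
}

# regions of `exons` lying outside `ref_union`, clipped to `span`
exonic_outside <- function(exons, ref_union, span) {
  pieces <- list()
  for (i in seq_len(nrow(exons))) {
    s <- max(exons[i, 1L], span[1L]); e <- min(exons[i, 2L], span[2L])
    if (e <= s) next
    cur_s <- s
    cover <- ref_union[ref_union[, 2L] > s & ref_union[, 1L] < e, , drop = FALSE]
    if (nrow(cover)) for (j in seq_len(nrow(cover))) {
      if (cover[j, 1L] > cur_s)
        pieces[[length(pieces) + 1L]] <- c(cur_s, cover[j, 1L])
      cur_s <- max(cur_s, cover[j, 2L])
    }
    if (cur_s < e) pieces[[length(pieces) + 1L]] <- c(cur_s, e)
  }
  if (!length(pieces))
    return(matrix(numeric(0), ncol = 2L))
  matrix(unlist(pieces), ncol = 2L, byrow = TRUE)
}

three_prime_end <- function(model) if (model$strand == "+") model$end else model$start

#' Classify an isoform as known or novel within its locus
#'
#' Known means: some locus reference transcript has an identical intron chain
#' and a 3' terminus within `end_tolerance` bases (long-read 3' ends jitter,
#' so exact end matching would call everything novel). Otherwise the isoform
#' is novel with the first applicable reason: `novel_locus` (the locus itself
#' is novel, so no reference structure exists to compare against),
#' `new_intron` (an intron absent from every locus reference transcript),
#' `new_exon` (an exonic region more than `end_tolerance` bases outside the
#' reference exon union, restricted to the locus reference span so terminal
#' extensions are not miscalled as new exons), or `changed_3prime_end`
#' (structure otherwise explained by a reference transcript but the 3' end
#' moved beyond tolerance).
#'
#' @param model A `transcript_model` assigned to `locus`.
#' @param locus The [gene_locus()] it was assigned to.
#' @param end_tolerance Bases of 3'-end slack (default 50).
#' @return List with `transcript_id`, `status` (`"known"`/`"novel"`) and
#'   `reason`.
#' @export
classify_isoform_status <- function(model, locus, end_tolerance = 50) {
  res <- function(status, reason)
    list(transcript_id = model$transcript_id, status = status, reason = reason)
  if (locus$status == "novel") return(res("novel", "novel_locus"))
  refs <- locus$transcripts
  chain <- intron_keys(model)
  for (tx in refs) {
    if (identical(intron_keys(tx), chain) &&
        abs(three_prime_end(model) - three_prime_end(tx)) <= end_tolerance)
      return(res("known", "matches_reference"))
  }
  ref_introns <- unique(unlist(lapply(refs, intron_keys)))
  if (length(setdiff(chain, ref_introns)))
    return(res("novel", "new_intron"))
  ref_union <- merge_intervals(do.call(rbind, lapply(refs, `[[`, "exons")))
  span <- c(min(vapply(refs, `[[`, 0, "start")),
            max(vapply(refs, `[[`, 0, "end")))
  outside <- exonic_outside(model$exons, ref_union, span)
  if (nrow(outside) && any(outside[, 2L] - outside[, 1L] > end_tolerance))
    return(res("novel", "new_exon"))
  res("novel", "changed_3prime_end")
}

strip_chr <- function(chrom) sub("^chr", "", chrom)

#' Merge classified representatives into an updated annotation
#'
#' Known isoforms are dropped (they would duplicate reference records); novel
#' isoforms are appended to their assigned loci and novel loci are appended
#' whole. Novel transcripts get ids `<chrom>.<locus index>.<isoform index>`
#' (chromosome prefix stripped of `"chr"`), with locus indices numbering loci
#' per chromosome in start order on the final locus set.
#'
#' @param reference Reference [genome_annotation()].
#' @param representatives List of [flnc_candidate()]s.
#' @param statuses List of status records from [classify_isoform_status()],
#'   parallel to `representatives`.
#' @param assignments Assignment data frame from [assign_loci()].
#' @param novel_loci Novel locus shells from [assign_loci()].
#' @return The updated [genome_annotation()].
#' @export
merge_annotation <- function(reference, representatives, statuses,
                             assignments, novel_loci = list()) {
  loci <- reference$loci
  for (locus in novel_loci) {
    # shell transcripts are re-added below with canonical ids
    locus$transcripts <- list()
    loci[[locus$gene_id]] <- locus
  }
  # final per-chromosome locus indices in start order
  chroms <- vapply(loci, `[[`, "", "chrom")
  starts <- vapply(loci, `[[`, 0, "start")
  locus_index <- integer(length(loci)); names(locus_index) <- names(loci)
  for (cc in unique(chroms)) {
    here <- which(chroms == cc)
    locus_index[here[order(starts[here])]] <- seq_along(here)
  }
  existing_ids <- unlist(lapply(reference$loci, function(l)
    vapply(l$transcripts, `[[`, "", "transcript_id")))
  iso_counter <- vapply(loci, function(l) length(l$transcripts), 0L)
  names(iso_counter) <- names(loci)

  for (i in seq_along(representatives)) {
    st <- statuses[[i]]
    if (st$status == "known") next
    gid <- assignments$gene_id[assignments$candidate_id ==
                                 representatives[[i]]$candidate_id]
    locus <- loci[[gid]]
    iso_counter[gid] <- iso_counter[gid] + 1L
    tid <- paste0(strip_chr(locus$chrom), ".", locus_index[gid], ".",
                  iso_counter[gid])
    while (tid %in% existing_ids) tid <- paste0(tid, "a")
    existing_ids <- c(existing_ids, tid)
    m <- representatives[[i]]$model
    m$transcript_id <- tid
    m$gene_id <- gid
    m$source <- "isoseq"
    locus$transcripts <- c(locus$transcripts, list(m))
    locus$start <- min(locus$start, m$start)
    locus$end <- max(locus$end, m$end)
    loci[[gid]] <- locus
  }
  loci <- Filter(function(l) length(l$transcripts) > 0L, loci)
  chrom_reg <- reference$chromosomes
  new_max <- vapply(loci, `[[`, 0, "end")
  for (k in seq_along(loci)) {
    cc <- loci[[k]]$chrom
    if (!cc %in% names(chrom_reg) || chrom_reg[[cc]] < new_max[k])
      chrom_reg[cc] <- new_max[k]
  }
  loci <- lapply(loci, function(l) gene_locus(l$gene_id, l$transcripts, l$status))
  genome_annotation(loci, chromosomes = chrom_reg)
}

#' Run the full catalog update: retain, collapse, assign, classify, merge
#'
#' @param reference Reference [genome_annotation()].
#' @param candidates List of [flnc_candidate()]s.
#' @param junctions A [junction_set()].
#' @param pid_threshold Passed to [retain_candidates()].
#' @param min_fraction Overlap linking threshold (collapse and assignment).
#' @param end_tolerance Passed to [classify_isoform_status()].
#' @return List with `annotation` (the updated annotation) and `decisions`, a
#'   per-candidate data frame (`candidate_id`, `kept`, `criteria`,
#'   `representative_id`, `gene_id`, `status`, `reason`).
#' @export
update_annotation <- function(reference, candidates, junctions,
                              pid_threshold = 99, min_fraction = 0.2,
                              end_tolerance = 50) {
  ret <- retain_candidates(candidates, junctions, reference, pid_threshold)
  kept <- candidates[ret$kept]
  coll <- collapse_redundant(kept, min_fraction)
  asg <- assign_loci(coll$representatives, reference, min_fraction)
  all_loci <- c(reference$loci, asg$novel_loci)
  statuses <- vector("list", length(coll$representatives))
  for (i in seq_along(coll$representatives)) {
    gid <- asg$assignments$gene_id[i]
    statuses[[i]] <- classify_isoform_status(coll$representatives[[i]]$model,
                                             all_loci[[gid]], end_tolerance)
  }
  updated <- merge_annotation(reference, coll$representatives, statuses,
                              asg$assignments, asg$novel_loci)
  decisions <- ret
  decisions$representative_id <- coll$membership$representative_id[
    match(decisions$candidate_id, coll$membership$candidate_id)]
  rep_ids <- vapply(coll$representatives, function(x) x$candidate_id, "")
  ri <- match(decisions$representative_id, rep_ids)
  decisions$gene_id <- asg$assignments$gene_id[ri]
  decisions$status <- vapply(statuses, function(s) s$status, "")[ri]
  decisions$reason <- vapply(statuses, function(s) s$reason, "")[ri]
  list(annotation = updated, decisions = decisions,
       representatives = coll$representatives, statuses = statuses,
       assignments = asg$assignments)
}
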