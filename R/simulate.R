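## Synthetic-data generators: a reference annotation, FLNC candidates with
## planted splicing perturbations, short-read junction sets with incomplete
## support, NB count matrices with planted fold changes, and peak sets placed
## across feature categories -- each with a ground-truth table, and all pure
## functions of (config, seed).

#' Simulation configuration
#'
#' Defaults emulate the two-crossbred-group lamb muscle design: three
#' samples per group, a 10% differentially expressed fraction at
#' |log2FC| = 2, NB dispersion 0.1 and log-normal(log 100, 1) baseline
#' expression; long-read candidates mix faithful copies with perturbed
#' transcripts carrying exactly one planted splicing change. Chromosomes are
#' named `chr1..chrN` with the last one `chrX` to exercise non-numeric
#' naming.
#'
#' @param seed Base RNG seed; every generator derives its stream from it.
#' @param n_genes,n_chromosomes Number of gene loci and chromosomes.
#' @param chromosome_length Optional fixed chromosome length (bases); packing
#'   that overflows it is an error. `NULL` sizes chromosomes to fit.
#' @param exon_count_min,exon_count_mean Exon count per transcript:
#'   `min + Poisson(mean - min)`, capped at 10.
#' @param exon_length_range,intron_length_range Uniform ranges (bases).
#' @param utr_probability Chance a transcript carries annotated UTRs.
#' @param n_candidates Number of FLNC candidates to emit.
#' @param novel_fraction Fraction of candidates carrying a perturbation.
#' @param event_mix Named proportions over `exon_skipping`,
#'   `intron_retention`, `alt_5ss`, `alt_3ss`, `mutually_exclusive`; must sum
#'   to 1.
#' @param shift3_fraction Fraction of novel candidates perturbed by a 3'-end
#'   shift instead of a splicing event.
#' @param flnc_mu,flnc_size FLNC read support is `1 + NB(mu - 1, size)`.
#' @param pid_shape,pid_scale PID is `100 - Gamma(shape, scale)`, clamped to
#'   `[85, 100]`.
#' @param junction_support_prob Chance each true intron enters the
#'   short-read junction set.
#' @param n_samples Samples per group for isoform counts.
#' @param n_features Features for [simulate_counts()] when ids are not given.
#' @param de_fraction,planted_lfc Differential fraction and planted
#'   |log2 fold change|.
#' @param nb_dispersion NB dispersion of simulated counts.
#' @param baseline_log_mean,baseline_log_sd Log-normal baseline expression.
#' @param library_size_sd SD of log-normal per-sample depth factors.
#' @param n_peaks,diff_peak_fraction,peak_lfc Peak count, differential
#'   fraction and planted peak enrichment.
#' @param peak_mix Named placement proportions over the six feature
#'   categories; must sum to 1. The default gives `five_prime_utr` weight 0:
#'   with the default symmetric promoter window the promoter category always
#'   shadows the 5' UTR under midpoint priority.
#' @param peak_samples_per_group Replicates per condition for peak counts.
#' @param peak_baseline_log_mean,peak_baseline_log_sd,peak_width_range Peak
#'   count baseline and width parameters.
#' @param promoter_upstream,promoter_downstream Promoter window used for
#'   peak placement truth.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 60, n_chromosomes = 3,
                       chromosome_length = NULL,
                       exon_count_min = 4, exon_count_mean = 6,
                       exon_length_range = c(80, 300),
                       intron_length_range = c(250, 1500),
                       utr_probability = 0.7,
                       n_candidates = 150, novel_fraction = 0.5,
                       event_mix = c(exon_skipping = 0.3,
                                     intron_retention = 0.25,
                                     alt_5ss = 0.15, alt_3ss = 0.15,
                                     mutually_exclusive = 0.15),
                       shift3_fraction = 0.2,
                       flnc_mu = 2.5, flnc_size = 1,
                       pid_shape = 2, pid_scale = 0.8,
                       junction_support_prob = 0.85,
                       n_samples = 3, n_features = 2000,
                       de_fraction = 0.1, planted_lfc = 2,
                       nb_dispersion = 0.1,
                       baseline_log_mean = log(100), baseline_log_sd = 1,
                       library_size_sd = 0.15,
                       n_peaks = 200, diff_peak_fraction = 0.2, peak_lfc = 3,
                       peak_mix = c(promoter = 0.3, five_prime_utr = 0,
                                    three_prime_utr = 0.1, exon = 0.15,
                                    intron = 0.2, intergenic = 0.25),
                       peak_samples_per_group = 3,
                       peak_baseline_log_mean = log(50),
                       peak_baseline_log_sd = 0.7,
                       peak_width_range = c(200, 500),
                       promoter_upstream = 3000, promoter_downstream = 3000) {
  cfg <- as.list(environment())
  probs <- c(utr_probability, novel_fraction, shift3_fraction,
             junction_support_prob, de_fraction, diff_peak_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(event_mix) - 1) > 1e-9) stop("event_mix must sum to 1")
  if (abs(sum(peak_mix) - 1) > 1e-9) stop("peak_mix must sum to 1")
  if (!all(names(peak_mix) %in% FEATURE_CATEGORIES))
    stop("peak_mix names must be feature categories")
  structure(cfg, class = "sim_config")
}

sim_chrom_names <- function(n) {
  if (n == 1L) return("chr1")
  c(paste0("chr", seq_len(n - 1L)), "chrX")
}

runif_int <- function(n, range) {
  floor(runif(n, range[1L], range[2L] + 1))
}

#' Simulate a reference genome annotation
#'
#' Places non-overlapping gene loci sequentially along each chromosome with
#' 10-30 kb intergenic gaps, each locus holding 1-3 transcripts (a primary
#' exon chain plus possible 3'-truncated isoforms) and, with configured
#' probability, terminal-exon UTR records. Deterministic for a fixed config.
#'
#' @param config A [sim_config()].
#' @return A [genome_annotation()].
#' @export
simulate_reference_annotation <- function(config) {
  set.seed(config$seed)
  chroms <- sim_chrom_names(config$n_chromosomes)
  per <- rep(floor(config$n_genes / length(chroms)), length(chroms))
  rem <- config$n_genes - sum(per)
  if (rem > 0) per[seq_len(rem)] <- per[seq_len(rem)] + 1L
  loci <- list()
  gene_no <- 0L
  chrom_len <- numeric(0)
  for (ci in seq_along(chroms)) {
    cursor <- 20000
    for (k in seq_len(per[ci])) {
      gene_no <- gene_no + 1L
      gid <- sprintf("GENE%04d", gene_no)
      cursor <- cursor + runif_int(1L, c(10000, 30000))
      strand <- sample(c("+", "-"), 1L)
      n_ex <- min(10L, config$exon_count_min +
                    rpois(1L, max(0, config$exon_count_mean -
                                    config$exon_count_min)))
      ex_len <- runif_int(n_ex, config$exon_length_range)
      in_len <- runif_int(max(0L, n_ex - 1L), config$intron_length_range)
      starts <- cursor + cumsum(c(0, ex_len[-n_ex] + in_len))
      exons <- cbind(start = starts, end = starts + ex_len)
      txs <- list()
      mk_utr <- function(exm) {
        if (runif(1L) >= config$utr_probability) return(list(u5 = NULL, u3 = NULL))
        l5 <- min(50, exm[1L, 2L] - exm[1L, 1L] - 10)
        l3 <- min(50, exm[nrow(exm), 2L] - exm[nrow(exm), 1L] - 10)
        left <- matrix(c(exm[1L, 1L], exm[1L, 1L] + l5), ncol = 2L)
        right <- matrix(c(exm[nrow(exm), 2L] - l3, exm[nrow(exm), 2L]), ncol = 2L)
        if (strand == "+") list(u5 = left, u3 = right)
        else list(u5 = right, u3 = left)
      }
      u <- mk_utr(exons)
      txs[[1L]] <- transcript_model(paste0(gid, ".t1"), chroms[ci], strand,
                                    exons, gene_id = gid,
                                    utr5 = u$u5, utr3 = u$u3)
      n_tx <- sample.int(3L, 1L)
      if (n_tx > 1L && n_ex >= 3L) {
        kept <- sort(sample(2L:(n_ex - 1L), min(n_tx - 1L, n_ex - 2L)),
                     decreasing = TRUE)
        for (t_i in seq_along(kept)) {
          sub <- exons[seq_len(kept[t_i]), , drop = FALSE]
          u2 <- mk_utr(sub)
          txs[[length(txs) + 1L]] <-
            transcript_model(paste0(gid, ".t", t_i + 1L), chroms[ci], strand,
                             sub, gene_id = gid, utr5 = u2$u5, utr3 = u2$u3)
        }
      }
      loci[[gid]] <- gene_locus(gid, txs, status = "known")
      cursor <- max(exons[, 2L])
    }
    len <- cursor + 50000
    if (!is.null(config$chromosome_length)) {
      if (cursor > config$chromosome_length)
        stop("infeasible packing: ", per[ci], " genes exceed chromosome ",
             "length ", config$chromosome_length, " on ", chroms[ci])
      len <- config$chromosome_length
    }
    chrom_len[chroms[ci]] <- len
  }
  genome_annotation(loci, chromosomes = chrom_len)
}

# apply one named perturbation to a transcript model; NULL when ineligible
perturb_transcript <- function(model, type, config) {
  ex <- model$exons
  n <- nrow(ex)
  new_ex <- NULL
  if (type == "exon_skipping") {
    if (n < 3L) return(NULL)
    i <- if (n == 3L) 2L else sample(2L:(n - 1L), 1L)
    new_ex <- ex[-i, , drop = FALSE]
  } else if (type == "intron_retention") {
    if (n < 2L) return(NULL)
    k <- if (n == 2L) 1L else sample(seq_len(n - 1L), 1L)
    merged <- c(ex[k, 1L], ex[k + 1L, 2L])
    new_ex <- rbind(ex[seq_len(n)[-c(k, k + 1L)], , drop = FALSE], merged)
  } else if (type %in% c("alt_5ss", "alt_3ss")) {
    if (n < 2L) return(NULL)
    k <- if (n == 2L) 1L else sample(seq_len(n - 1L), 1L)
    delta <- sample(8:30, 1L)
    # which physical boundary is 5' depends on the strand
    move_left <- (type == "alt_5ss") == (model$strand == "+")
    new_ex <- ex
    if (move_left) {
      # shift the donor-side boundary (end of exon k)
      if (runif(1L) < 0.5 && ex[k, 2L] - ex[k, 1L] - delta >= 20) {
        new_ex[k, 2L] <- ex[k, 2L] - delta
      } else if (ex[k + 1L, 1L] - ex[k, 2L] - delta >= 30) {
        new_ex[k, 2L] <- ex[k, 2L] + delta
      } else return(NULL)
    } else {
      # shift the acceptor-side boundary (start of exon k+1)
      if (runif(1L) < 0.5 && ex[k + 1L, 2L] - ex[k + 1L, 1L] - delta >= 20) {
        new_ex[k + 1L, 1L] <- ex[k + 1L, 1L] + delta
      } else if (ex[k + 1L, 1L] - ex[k, 2L] - delta >= 30) {
        new_ex[k + 1L, 1L] <- ex[k + 1L, 1L] - delta
      } else return(NULL)
    }
  } else if (type == "mutually_exclusive") {
    if (n < 3L) return(NULL)
    cands <- sample(2L:(n - 1L))
    for (i in cands) {
      gap_s <- ex[i, 2L]; gap_e <- ex[i + 1L, 1L]
      new_len <- runif_int(1L, c(80, 150))
      if (gap_e - gap_s < new_len + 40) next
      b <- gap_s + runif_int(1L, c(20, gap_e - gap_s - new_len - 20))
      new_ex <- rbind(ex[-i, , drop = FALSE], c(b, b + new_len))
      break
    }
    if (is.null(new_ex)) return(NULL)
  } else if (type == "shift3") {
    delta <- sample(80:300, 1L)
    new_ex <- ex
    if (model$strand == "+") {
      if (runif(1L) < 0.5 && ex[n, 2L] - ex[n, 1L] - delta >= 20)
        new_ex[n, 2L] <- ex[n, 2L] - delta
      else new_ex[n, 2L] <- ex[n, 2L] + delta
    } else {
      if (runif(1L) < 0.5 && ex[1L, 2L] - ex[1L, 1L] - delta >= 20)
        new_ex[1L, 1L] <- ex[1L, 1L] + delta
      else new_ex[1L, 1L] <- max(0, ex[1L, 1L] - delta)
    }
  } else stop("unknown perturbation type '", type, "'")
  transcript_model(model$transcript_id, model$chrom, model$strand, new_ex,
                   source = "isoseq")
}

perturbation_reason <- c(exon_skipping = "new_intron",
                         intron_retention = "new_exon",
                         alt_5ss = "new_intron", alt_3ss = "new_intron",
                         mutually_exclusive = "new_intron",
                         shift3 = "changed_3prime_end")

#' Simulate FLNC isoform candidates with planted perturbations
#'
#' Each candidate copies a random reference transcript; with probability
#' `novel_fraction` it instead carries exactly one planted change: a 3'-end
#' shift (probability `shift3_fraction` among novel candidates) or one
#' splicing perturbation drawn from `event_mix`. Read counts and PIDs come
#' from the configured distributions. The truth table records the source
#' transcript, planted perturbation and expected novelty reason.
#'
#' @param reference A [genome_annotation()] from
#'   [simulate_reference_annotation()].
#' @param config A [sim_config()].
#' @return List with `candidates` (list of [flnc_candidate()]) and `truth`
#'   (data frame: `candidate_id`, `source_transcript`, `true_status`,
#'   `planted`, `true_reason`, `flnc_read_count`, `percent_identity`).
#' @export
simulate_flnc_candidates <- function(reference, config) {
  set.seed(config$seed + 1L)
  txs <- annotation_transcripts(reference)
  # 3' shifts are only planted on transcripts forming their locus's 3'
  # extreme: shifting an internal isoform's end would poke into sibling
  # exon/intron territory and be (correctly) read as a new exon, making the
  # planted truth ambiguous
  at_3prime_edge <- vapply(txs, function(t) {
    locus <- reference$loci[[t$gene_id]]
    if (t$strand == "+") t$end >= locus$end else t$start <= locus$start
  }, TRUE)
  cands <- vector("list", config$n_candidates)
  truth <- vector("list", config$n_candidates)
  for (j in seq_len(config$n_candidates)) {
    cid <- sprintf("FLNC%05d", j)
    novel <- runif(1L) < config$novel_fraction
    planted <- NA_character_
    model <- NULL
    if (novel) {
      for (try in 1:50) {
        type <- if (runif(1L) < config$shift3_fraction) "shift3"
        else sample(names(config$event_mix), 1L, prob = config$event_mix)
        src <- txs[[sample.int(length(txs), 1L)]]
        if (type == "shift3" &&
            !at_3prime_edge[[match(src$transcript_id,
                                   vapply(txs, `[[`, "", "transcript_id"))]])
          next
        model <- perturb_transcript(src, type, config)
        if (is.null(model)) next
        # reject perturbations whose product collides with a sibling
        # reference isoform (e.g. retaining the last intron of a transcript
        # reproduces a truncated isoform's chain): the planted novelty would
        # be ambiguous
        locus <- reference$loci[[src$gene_id]]
        ambiguous <- any(vapply(locus$transcripts, function(t)
          identical(intron_keys(t), intron_keys(model)) &&
            abs(three_prime_end(model) - three_prime_end(t)) <= 50, TRUE))
        if (ambiguous) { model <- NULL; next }
        planted <- type
        break
      }
      if (is.null(model)) stop("could not place perturbation after 50 tries")
    } else {
      src <- txs[[sample.int(length(txs), 1L)]]
      model <- transcript_model(src$transcript_id, src$chrom, src$strand,
                                src$exons, source = "isoseq")
    }
    model$transcript_id <- cid
    count <- 1 + rnbinom(1L, mu = max(0.01, config$flnc_mu - 1),
                         size = config$flnc_size)
    pid <- round(pmin(100, pmax(85, 100 - rgamma(1L, shape = config$pid_shape,
                                                 scale = config$pid_scale))), 3)
    cands[[j]] <- flnc_candidate(cid, model, count, pid)
    truth[[j]] <- data.frame(
      candidate_id = cid, source_transcript = src$transcript_id,
      true_status = if (novel) "novel" else "known",
      planted = planted,
      true_reason = if (novel) unname(perturbation_reason[planted])
      else "matches_reference",
      flnc_read_count = count, percent_identity = pid,
      stringsAsFactors = FALSE)
  }
  list(candidates = cands, truth = do.call(rbind, truth))
}

#' Simulate a short-read splice-junction set with incomplete support
#'
#' Every true intron (reference transcripts plus candidate models) enters
#' the set independently with probability `junction_support_prob`.
#'
#' @param reference A [genome_annotation()].
#' @param candidates Optional list of [flnc_candidate()]s whose introns are
#'   also eligible.
#' @param config A [sim_config()].
#' @return A [junction_set()] (possibly with zero rows).
#' @export
simulate_junctions <- function(reference, candidates = list(), config) {
  set.seed(config$seed + 2L)
  models <- c(annotation_transcripts(reference),
              lapply(candidates, `[[`, "model"))
  rows <- lapply(models, function(m) {
    ic <- intron_chain(m)
    if (!nrow(ic)) return(NULL)
    data.frame(chrom = m$chrom, start = ic[, 1L], end = ic[, 2L],
               strand = m$strand, stringsAsFactors = FALSE)
  })
  df <- unique(do.call(rbind, rows))
  if (is.null(df) || !nrow(df))
    return(junction_set(data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0), strand = character(0))))
  df <- df[order(df$chrom, df$start, df$end, df$strand), , drop = FALSE]
  keep <- runif(nrow(df)) < config$junction_support_prob
  junction_set(df[keep, , drop = FALSE])
}

#' Simulate a two-group NB count matrix with planted fold changes
#'
#' Baseline means are log-normal; a `de_fraction` of features carries
#' `planted_lfc` with random sign in the second group; per-sample depth
#' factors are log-normal. Counts are NB with the configured dispersion.
#'
#' @param feature_ids Character vector of feature ids, or `NULL` to use
#'   `config$n_features` synthetic ids.
#' @param config A [sim_config()].
#' @param group_labels Two group names (defaults `DDH`, `DHH`).
#' @return List with `counts` (a [count_matrix()]) and `truth` (data frame:
#'   `feature_id`, `is_de`, `true_log2fc`).
#' @export
simulate_counts <- function(feature_ids = NULL, config,
                            group_labels = c("DDH", "DHH")) {
  set.seed(config$seed + 3L)
  if (is.null(feature_ids))
    feature_ids <- sprintf("ISO%05d", seq_len(config$n_features))
  nf <- length(feature_ids)
  if (nf < 1L) stop("at least one feature is required")
  n <- config$n_samples
  de <- logical(nf)
  de[sample.int(nf, round(config$de_fraction * nf))] <- TRUE
  sgn <- sample(c(-1, 1), nf, replace = TRUE)
  lfc <- ifelse(de, config$planted_lfc * sgn, 0)
  mu1 <- exp(rnorm(nf, config$baseline_log_mean, config$baseline_log_sd))
  mu2 <- mu1 * 2^lfc
  depth <- exp(rnorm(2L * n, 0, config$library_size_sd))
  mu_mat <- cbind(matrix(rep(mu1, n), nf), matrix(rep(mu2, n), nf))
  mu_mat <- sweep(mu_mat, 2L, depth, "*")
  counts <- matrix(rnbinom(nf * 2L * n, mu = mu_mat,
                           size = 1 / config$nb_dispersion), nf)
  rownames(counts) <- feature_ids
  colnames(counts) <- c(paste0(group_labels[1L], "_", seq_len(n)),
                        paste0(group_labels[2L], "_", seq_len(n)))
  cm <- count_matrix(counts, rep(group_labels, each = n))
  list(counts = cm,
       truth = data.frame(feature_id = feature_ids, is_de = de,
                          true_log2fc = lfc, stringsAsFactors = FALSE))
}

# integer positions inside `intervals` (matrix) but outside any `exclude`
# interval; returns a matrix of allowed sub-intervals
subtract_intervals <- function(intervals, exclude) {
  if (!nrow(intervals)) return(intervals)
  if (!nrow(exclude)) return(intervals)
  exclude <- merge_intervals(exclude)
  out <- list()
  for (i in seq_len(nrow(intervals))) {
    cur <- intervals[i, 1L]; e <- intervals[i, 2L]
    hits <- exclude[exclude[, 2L] > cur & exclude[, 1L] < e, , drop = FALSE]
    if (nrow(hits)) for (j in seq_len(nrow(hits))) {
      if (hits[j, 1L] > cur) out[[length(out) + 1L]] <- c(cur, hits[j, 1L])
      cur <- max(cur, hits[j, 2L])
    }
    if (cur < e) out[[length(out) + 1L]] <- c(cur, e)
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 2L))
  matrix(unlist(out), ncol = 2L, byrow = TRUE)
}

sample_position <- function(intervals) {
  if (!nrow(intervals)) return(NA_real_)
  sizes <- intervals[, 2L] - intervals[, 1L]
  i <- sample.int(nrow(intervals), 1L, prob = sizes)
  floor(runif(1L, intervals[i, 1L], intervals[i, 2L]))
}

#' Simulate ChIP-seq peak sets with planted feature placement and
#' differential binding
#'
#' Peak midpoints are placed by the configured category mix (the true
#' category is recorded); counts are NB across two conditions with a planted
#' differential fraction enriched in one of them.
#'
#' @param annotation A [genome_annotation()].
#' @param config A [sim_config()].
#' @return List with `peaks` (list of [peak()]), `counts` (a
#'   [count_matrix()]), `bed` (data frame of intervals) and `truth` (data
#'   frame: `peak_id`, `true_category`, `gene_id`, `is_differential`,
#'   `direction`).
#' @export
simulate_peaksets <- function(annotation, config) {
  set.seed(config$seed + 4L)
  up <- config$promoter_upstream; down <- config$promoter_downstream
  index <- build_feature_index(annotation, up, down)
  by_chrom <- split(index, vapply(index, `[[`, "", "chrom"))
  windows_of <- function(chrom) {
    w <- do.call(rbind, lapply(by_chrom[[chrom]], `[[`, "promoter"))
    if (is.null(w)) matrix(numeric(0), ncol = 2L) else w
  }
  # category -> candidate position intervals for one random eligible gene
  position_pool <- function(category) {
    if (category == "intergenic") {
      cc <- sample(names(annotation$chromosomes), 1L)
      blocked <- rbind(windows_of(cc),
                       do.call(rbind, c(lapply(by_chrom[[cc]], `[[`, "span"),
                                        list(matrix(numeric(0), ncol = 2L)))))
      blocked <- if (nrow(blocked)) merge_intervals(blocked) else blocked
      whole <- matrix(c(1000, annotation$chromosomes[[cc]] - 1000), ncol = 2L)
      allowed <- subtract_intervals(whole, blocked)
      # keep a margin so widths never leak into gene territory
      allowed <- allowed[allowed[, 2L] - allowed[, 1L] > 2000, , drop = FALSE]
      if (nrow(allowed)) {
        allowed[, 1L] <- allowed[, 1L] + 500
        allowed[, 2L] <- allowed[, 2L] - 500
      }
      attr(allowed, "gene_id") <- NA_character_
      attr(allowed, "chrom") <- cc
      return(allowed)
    }
    g <- index[[sample.int(length(index), 1L)]]
    win <- windows_of(g$chrom)
    pool <- switch(category,
      promoter = matrix(c(max(0, g$promoter[1L] + 50), g$promoter[2L] - 50),
                        ncol = 2L),
      five_prime_utr = subtract_intervals(g$utr5, win),
      three_prime_utr = subtract_intervals(g$utr3, win),
      exon = subtract_intervals(
        subtract_intervals(g$exons, rbind(g$utr5, g$utr3)), win),
      intron = subtract_intervals(
        subtract_intervals(matrix(g$span, ncol = 2L), g$exons), win))
    attr(pool, "gene_id") <- g$gene_id
    attr(pool, "chrom") <- g$chrom
    pool
  }
  n <- config$n_peaks
  cats <- sample(names(config$peak_mix), n, replace = TRUE,
                 prob = config$peak_mix)
  peaks <- vector("list", n)
  truth <- vector("list", n)
  is_diff <- logical(n)
  is_diff[sample.int(n, round(config$diff_peak_fraction * n))] <- TRUE
  for (i in seq_len(n)) {
    pos <- NA; gene <- NA_character_; chrom <- NA_character_
    for (try in 1:100) {
      pool <- position_pool(cats[i])
      pos <- sample_position(pool)
      if (!is.na(pos)) {
        gene <- attr(pool, "gene_id")
        chrom <- attr(pool, "chrom")
        break
      }
    }
    if (is.na(pos)) stop("could not place a '", cats[i], "' peak; ",
                         "check the annotation carries that feature")
    w <- runif_int(1L, config$peak_width_range)
    start <- max(0, pos - floor(w / 2))
    pk_id <- sprintf("PEAK%05d", i)
    peaks[[i]] <- peak(pk_id, chrom, start, start + w)
    truth[[i]] <- data.frame(peak_id = pk_id, true_category = cats[i],
                             gene_id = gene, is_differential = is_diff[i],
                             stringsAsFactors = FALSE)
  }
  ns <- config$peak_samples_per_group
  mu <- exp(rnorm(n, config$peak_baseline_log_mean, config$peak_baseline_log_sd))
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  lfc <- ifelse(is_diff, config$peak_lfc * sgn, 0)
  mu2 <- mu * 2^lfc
  counts <- cbind(matrix(rnbinom(n * ns, mu = rep(mu, ns),
                                 size = 1 / config$nb_dispersion), n),
                  matrix(rnbinom(n * ns, mu = rep(mu2, ns),
                                 size = 1 / config$nb_dispersion), n))
  rownames(counts) <- vapply(peaks, `[[`, "", "peak_id")
  colnames(counts) <- c(paste0("DDH_", seq_len(ns)),
                        paste0("DHH_", seq_len(ns)))
  truth <- do.call(rbind, truth)
  truth$direction <- ifelse(truth$is_differential,
                            ifelse(lfc > 0, "up", "down"), NA_character_)
  bed <- data.frame(chrom = vapply(peaks, `[[`, "", "chrom"),
                    start = vapply(peaks, `[[`, 0, "start"),
                    end = vapply(peaks, `[[`, 0, "end"),
                    peak_id = vapply(peaks, `[[`, "", "peak_id"),
                    stringsAsFactors = FALSE)
  list(peaks = peaks,
       counts = count_matrix(counts, rep(c("DDH", "DHH"), each = ns)),
       bed = bed, truth = truth)
}

#' Simulate reference/perturbed isoform pairs with one planted event each
#'
#' For classifier-recovery checks: each pair is a reference transcript and a
#' copy carrying exactly one planted splicing event of known type.
#'
#' @param n_pairs Number of pairs.
#' @param config A [sim_config()]; the event mix is renormalized over the
#'   five splicing types (no 3' shifts).
#' @return List of lists with elements `ref`, `alt` (transcript models) and
#'   `type`.
#' @export
simulate_perturbation_pairs <- function(n_pairs, config) {
  reference <- simulate_reference_annotation(config)
  set.seed(config$seed + 5L)
  txs <- Filter(function(tx) nrow(tx$exons) >= 4L,
                annotation_transcripts(reference))
  if (!length(txs)) stop("no transcript with >= 4 exons to perturb")
  mix <- config$event_mix / sum(config$event_mix)
  out <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    alt <- NULL
    for (try in 1:50) {
      type <- sample(names(mix), 1L, prob = mix)
      src <- txs[[sample.int(length(txs), 1L)]]
      alt <- perturb_transcript(src, type, config)
      if (!is.null(alt)) break
    }
    if (is.null(alt)) stop("could not plant an event after 50 tries")
    alt$transcript_id <- paste0(src$transcript_id, ".alt", i)
    out[[i]] <- list(ref = src, alt = alt, type = type)
  }
  out
}

#' Materialize a complete synthetic workspace on disk
#'
#' Writes every input the pipeline consumes -- reference GFF3, candidate
#' BED12 with a read-count/PID sidecar TSV, junction BED, isoform count and
#' group TSVs, peak BED and count TSVs -- plus ground-truth TSVs, including
#' the expected retention criteria per candidate given the emitted junction
#' set.
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @return Invisibly, a list with the generated objects and file `paths`.
#' @export
simulate_workspace <- function(dir, config = sim_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  reference <- simulate_reference_annotation(config)
  fl <- simulate_flnc_candidates(reference, config)
  junctions <- simulate_junctions(reference, fl$candidates, config)
  cnt <- simulate_counts(NULL, config)
  pks <- simulate_peaksets(reference, config)

  write_gff(reference, p("reference.gff3"))
  write_bed12(lapply(fl$candidates, `[[`, "model"), p("candidates.bed12"))
  info <- data.frame(
    candidate_id = vapply(fl$candidates, `[[`, "", "candidate_id"),
    flnc_read_count = vapply(fl$candidates, `[[`, 0, "flnc_read_count"),
    percent_identity = vapply(fl$candidates, `[[`, 0, "percent_identity"))
  write.table(info, p("candidates_info.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_junctions_bed(junctions, p("junctions.bed"))
  write.table(data.frame(feature_id = rownames(cnt$counts$counts),
                         cnt$counts$counts, check.names = FALSE),
              p("isoform_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample_id = colnames(cnt$counts$counts),
                         group = as.character(cnt$counts$groups)),
              p("groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pks$bed, p("peaks.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(peak_id = rownames(pks$counts$counts),
                         pks$counts$counts, check.names = FALSE),
              p("peak_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # expected retention outcome per candidate, from generator-side knowledge
  jkeys <- junction_set_keys(junctions)
  universe <- reference_intron_universe(reference)
  crit <- lapply(fl$candidates, function(cand) {
    ik <- intron_keys(cand$model)
    c(C1_multiread = cand$flnc_read_count >= 2,
      C2_single_read_high_pid = cand$flnc_read_count == 1 &&
        cand$percent_identity > 99,
      C3_junctions_supported = all(ik %in% jkeys),
      C4_events_annotated = all(ik %in% universe))
  })
  fl$truth$true_kept <- vapply(crit, any, TRUE)
  fl$truth$true_criteria <- vapply(crit, function(x)
    paste(names(x)[x], collapse = ","), "")
  write.table(fl$truth, p("truth_candidates.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cnt$truth, p("truth_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(pks$truth, p("truth_peaks.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(
    reference = reference, candidates = fl$candidates,
    candidate_truth = fl$truth, junctions = junctions,
    counts = cnt$counts, count_truth = cnt$truth,
    peaks = pks$peaks, peak_counts = pks$counts, peak_truth = pks$truth,
    paths = list(reference = p("reference.gff3"),
                 candidates = p("candidates.bed12"),
                 candidate_info = p("candidates_info.tsv"),
                 junctions = p("junctions.bed"),
                 isoform_counts = p("isoform_counts.tsv"),
                 groups = p("groups.tsv"), peaks = p("peaks.bed"),
                 peak_counts = p("peak_counts.tsv"))))
}
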