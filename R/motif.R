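# FIMO-style PWM scanning of probe-flanking windows: log-odds scoring against
# a 0-order background, exact score p-values by dynamic programming over
# quantized scores, and odds-ratio motif enrichment of probe sets.

#' Log-odds scoring matrix from a PWM
#'
#' Each entry is `log2(p_adj / background_b)` where the adjusted probability
#' applies a fixed pseudo-frequency: `p_adj = (p + pc * background_b) /
#' (1 + pc)`. The pseudo-frequency keeps zero-probability bases finite while
#' leaving well-supported probabilities essentially unchanged.
#'
#' @param pwm a PWM list (`motif_id`, `probs`) as from [read_meme_motifs()].
#' @param background length-4 base frequencies (A, C, G, T) summing to 1,
#'   all strictly positive.
#' @param pseudocount pseudo-frequency pc (default 0.001).
#' @return L x 4 numeric matrix (columns A, C, G, T).
#' @export
log_odds_matrix <- function(pwm, background = rep(0.25, 4),
                            pseudocount = 0.001) {
  stopifnot(abs(sum(background) - 1) < 1e-6)
  if (any(background <= 0))
    stop("background frequencies must all be positive", call. = FALSE)
  adj <- sweep(pwm$probs, 2, background * pseudocount, "+") / (1 + pseudocount)
  lom <- log2(sweep(adj, 2, background, "/"))
  dimnames(lom) <- list(NULL, c("A", "C", "G", "T"))
  lom
}

#' Exact null distribution of PWM window scores
#'
#' Quantizes the log-odds matrix onto an integer score grid and computes, by
#' dynamic programming over positions, the probability that an i.i.d.
#' background sequence of the motif's length scores at least `s`, for every
#' attainable quantized score `s`.
#'
#' @param lom L x 4 log-odds matrix from [log_odds_matrix()].
#' @param background length-4 base frequencies.
#' @param granularity score quantization step; default `range/1000` where
#'   range is the span between the minimal and maximal attainable score.
#' @return object of class `score_pvalue_table`: list with `qmat` (quantized
#'   integer matrix), `step`, `offset` (real score of quantized 0), and
#'   `pvals` (`pvals[q + 1] = P(score >= offset + q * step)`).
#' @export
score_pvalue_table <- function(lom, background = rep(0.25, 4),
                               granularity = NULL) {
  L <- nrow(lom)
  row_min <- apply(lom, 1, min)
  rng <- sum(apply(lom, 1, max)) - sum(row_min)
  if (is.null(granularity)) granularity <- if (rng > 0) rng / 1000 else 1
  stopifnot(granularity > 0)
  qmat <- round(sweep(lom, 1, row_min, "-") / granularity)
  storage.mode(qmat) <- "integer"
  qmax <- sum(apply(qmat, 1, max))
  dist <- numeric(qmax + 1L)  # index q+1 = P(quantized sum == q)
  dist[1] <- 1
  for (i in seq_len(L)) {
    nd <- numeric(qmax + 1L)
    for (b in 1:4) {
      s <- qmat[i, b]
      nd[(1 + s):(qmax + 1)] <- nd[(1 + s):(qmax + 1)] +
        background[b] * dist[1:(qmax + 1 - s)]
    }
    dist <- nd
  }
  pvals <- rev(cumsum(rev(dist)))
  pvals <- pmin(pvals, 1)
  structure(list(qmat = qmat, step = granularity, offset = sum(row_min),
                 pvals = pvals),
            class = "score_pvalue_table")
}

#' p-value of an observed window score
#' @param table a `score_pvalue_table`.
#' @param score real log-odds score.
#' @return `P(score' >= score)` under the background model.
#' @export
score_pvalue <- function(table, score) {
  q <- round((score - table$offset) / table$step)
  q <- pmin(pmax(q, 0L), length(table$pvals) - 1L)
  table$pvals[q + 1L]
}

# reverse-complement a quantized (or real) PWM-shaped matrix: reverse the
# positions and swap A<->T, C<->G
revcomp_matrix <- function(m) {
  out <- m[rev(seq_len(nrow(m))), c(4, 3, 2, 1), drop = FALSE]
  colnames(out) <- c("A", "C", "G", "T")
  out
}

# sliding quantized scores of a motif over an integer-coded sequence
# (1=A..4=T, NA for unknown); returns NA where any covered base is unknown
slide_scores <- function(qmat, seq_idx) {
  L <- nrow(qmat); W <- length(seq_idx)
  if (W < L) return(integer(0))
  P <- W - L + 1L
  ii <- outer(seq_len(L), seq_len(P) - 1L, "+")
  b <- seq_idx[ii]
  v <- matrix(qmat[cbind(rep(seq_len(L), P), as.vector(b))], nrow = L)
  colSums(v)
}

#' Scan probe-flanking windows for motif occurrences
#'
#' Scans the +/- `window` bp region around each probe's CpG on both strands
#' with every PWM, reporting positions whose exact background p-value is
#' below `p_max`. Positions covering an unknown base (N) are skipped.
#' Windows are truncated at contig ends.
#'
#' @param probes probe manifest data.frame (`id`, `chrom`, `pos`).
#' @param genome a `Biostrings::DNAStringSet` (names = chromosomes) or path
#'   to a FASTA file.
#' @param pwms list of PWMs as from [read_meme_motifs()].
#' @param window flank size in bp (default 100; window width 2*window+1).
#' @param p_max match p-value threshold (default 1e-4).
#' @param background length-4 base frequencies (default uniform).
#' @return data.frame of hits: `probe_id`, `motif_id`, `offset` (0-based
#'   match start relative to window start), `strand`, `score`, `p_match`.
#' @export
scan_windows <- function(probes, genome, pwms, window = 100, p_max = 1e-4,
                         background = rep(0.25, 4)) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  # FASTA headers may carry descriptions; use the first word
  names(genome) <- sub("\\s.*", "", names(genome))
  engines <- lapply(pwms, function(p) {
    lom <- log_odds_matrix(p, background)
    fwd <- score_pvalue_table(lom, background)
    rev_ <- score_pvalue_table(revcomp_matrix(lom), background)
    list(fwd = fwd, rev = rev_)
  })
  out <- list()
  for (i in seq_len(nrow(probes))) {
    ch <- probes$chrom[i]
    if (!ch %in% names(genome)) {
      warning(sprintf("probe %s: chromosome %s absent from genome; skipped",
                      probes$id[i], ch))
      next
    }
    clen <- Biostrings::width(genome[ch])
    lo <- max(1L, probes$pos[i] - window)
    hi <- min(clen, probes$pos[i] + window)
    s <- as.character(Biostrings::subseq(genome[[ch]], lo, hi))
    idx <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    for (mid in names(pwms)) {
      eng <- engines[[mid]]
      for (str in c("+", "-")) {
        tab <- if (str == "+") eng$fwd else eng$rev
        qs <- slide_scores(tab$qmat, idx)
        if (!length(qs)) next
        ok <- which(!is.na(qs))
        if (!length(ok)) next
        pv <- tab$pvals[qs[ok] + 1L]
        hit <- ok[pv < p_max]
        if (!length(hit)) next
        out[[length(out) + 1L]] <- data.frame(
          probe_id = probes$id[i], motif_id = mid,
          offset = hit - 1L, strand = str,
          score = tab$offset + qs[hit] * tab$step,
          p_match = tab$pvals[qs[hit] + 1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(probe_id = character(), motif_id = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), p_match = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Motif enrichment of a probe set against the enhancer background
#'
#' For each motif builds the per-probe contingency (a = probes in the
#' selected set with >= 1 occurrence, b = without; c, d = the same counts in
#' the background set) and evaluates
#' `OR = (p/(1-p)) / (P/(1-P))` with `p = a/(a+b)`, `P = c/(c+d)`,
#' `SD = sqrt(1/a + 1/b + 1/c + 1/d)` and
#' `lower_ci = exp(ln(OR) - z * SD)`.
#' A motif is flagged enriched iff `lower_ci > or_floor` and
#' `a >= min_occurrences`.
#'
#' @param paired_ids probe ids of the selected (gene-linked) set; must be a
#'   subset of `background_ids`.
#' @param background_ids probe ids of the full enhancer background.
#' @param hits hit data.frame from [scan_windows()].
#' @param or_floor lower-CI threshold (default 1.1).
#' @param min_occurrences minimum `a` (default 10).
#' @param z CI multiplier (default 1.96; use 1 for a one-SD bound).
#' @return data.frame ranked by decreasing OR: `motif_id`, `a`, `b`, `c`,
#'   `d`, `p_sel`, `p_bg`, `odds_ratio`, `sd`, `lower_ci`, `enriched`,
#'   `evaluable`.
#' @export
motif_enrichment <- function(paired_ids, background_ids, hits,
                             or_floor = 1.1, min_occurrences = 10,
                             z = 1.96) {
  paired_ids <- unique(paired_ids)
  background_ids <- unique(background_ids)
  if (!all(paired_ids %in% background_ids))
    stop("paired probe set must be a subset of the background set",
         call. = FALSE)
  motifs <- sort(unique(hits$motif_id))
  rows <- lapply(motifs, function(mid) {
    with_hit <- unique(hits$probe_id[hits$motif_id == mid])
    a <- sum(paired_ids %in% with_hit)
    b <- length(paired_ids) - a
    c_ <- sum(background_ids %in% with_hit)
    d <- length(background_ids) - c_
    if (min(a, b, c_, d) > 0) {
      p_sel <- a / (a + b); p_bg <- c_ / (c_ + d)
      or <- (p_sel / (1 - p_sel)) / (p_bg / (1 - p_bg))
      sdv <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
      lci <- exp(log(or) - z * sdv)
      evaluable <- TRUE
    } else {
      p_sel <- if (a + b > 0) a / (a + b) else NA_real_
      p_bg <- if (c_ + d > 0) c_ / (c_ + d) else NA_real_
      or <- NA_real_; sdv <- NA_real_; lci <- NA_real_
      evaluable <- FALSE
    }
    data.frame(motif_id = mid, a = a, b = b, c = c_, d = d,
               p_sel = p_sel, p_bg = p_bg, odds_ratio = or, sd = sdv,
               lower_ci = lci,
               enriched = evaluable && lci > or_floor && a >= min_occurrences,
               evaluable = evaluable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$odds_ratio), -Inf, out$odds_ratio),
                   out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
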