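# Probe-gene linking: one-sided Mann-Whitney tests comparing expression
# between the extreme methylation quintiles (M = most methylated 20 %,
# U = least methylated 20 %), corrected by a permutation empirical p-value
# drawn from distal non-enhancer probes.

# ---- Mann-Whitney core -------------------------------------------------------

#' One-sided Mann-Whitney p-value, alternative: values(M) < values(U)
#'
#' The U statistic counts (i, j) pairs with M_i > U_j (ties count 1/2). The
#' lower tail P(U <= u) is exact (stats::pwilcox) when the combined sample
#' size is at most `exact_max` and there are no ties; otherwise a normal
#' approximation with midranks, tie correction and continuity correction is
#' used. Returns 0.5 when all values are identical (no signal).
#'
#' @param m_vals numeric values of group M.
#' @param u_vals numeric values of group U.
#' @param exact_max largest combined sample size for the exact tail.
#' @return one-sided p-value in (0, 1].
#' @export
u_test <- function(m_vals, u_vals, exact_max = 12L) {
  m <- length(m_vals); n <- length(u_vals)
  stopifnot(m >= 1, n >= 1)
  comb <- c(m_vals, u_vals)
  r <- rank(comb)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(comb) > 0
  if ((m + n) <= exact_max && !ties)
    return(stats::pwilcox(u, m, n))
  N <- m + n
  tab <- tabulate(match(comb, unique(comb)))
  tiecor <- sum(tab^3 - tab)
  sig2 <- m * n / 12 * ((N + 1) - tiecor / (N * (N - 1)))
  if (sig2 <= 0) return(0.5)
  z <- (u - m * n / 2 + 0.5) / sqrt(sig2)
  stats::pnorm(z)
}

#' Methylation-expression association test for one probe-gene pair
#'
#' Splits samples into the M group (highest-beta `fraction`) and the U group
#' (lowest-beta `fraction`) by [extreme_indices()], then tests whether
#' expression in M is lower than in U ([u_test()]). Samples with missing
#' expression are dropped from their group after the split.
#'
#' @param probe_betas named numeric beta vector across samples.
#' @param gene_expr named numeric expression vector across the same samples.
#' @param fraction extreme-group proportion (default 0.2).
#' @return raw one-sided p-value `p_r`, or NULL if either group has fewer
#'   than 2 samples with non-missing expression.
#' @export
pair_utest <- function(probe_betas, gene_expr, fraction = 0.2) {
  iM <- extreme_indices(probe_betas, fraction, "high")
  iU <- extreme_indices(probe_betas, fraction, "low")
  xM <- gene_expr[iM]; xU <- gene_expr[iU]
  xM <- xM[!is.na(xM)]; xU <- xU[!is.na(xU)]
  if (length(xM) < 2 || length(xU) < 2) return(NULL)
  u_test(xM, xU)
}

# ---- variability filter ------------------------------------------------------

#' Methylation variability filter for a probe
#'
#' For hypomethylation calls, requires that at least `min_frac` of samples
#' (tumors and normals combined) have beta above `beta_thresh`, so there is
#' methylation headroom to lose; for hypermethylation the rule is mirrored
#' (at least `min_frac` below `beta_thresh`). Proportions are over
#' non-missing values.
#'
#' @param probe_betas numeric beta vector.
#' @param min_frac minimum proportion (default 0.05), boundary inclusive.
#' @param beta_thresh beta cutoff (default 0.3).
#' @param direction `"hypo"` or `"hyper"`.
#' @return logical.
#' @export
variability_filter <- function(probe_betas, min_frac = 0.05,
                               beta_thresh = 0.3,
                               direction = c("hypo", "hyper")) {
  direction <- match.arg(direction)
  v <- probe_betas[!is.na(probe_betas)]
  if (!length(v)) stop("all betas missing", call. = FALSE)
  prop <- if (direction == "hypo") mean(v > beta_thresh)
          else mean(v < beta_thresh)
  prop >= min_frac
}

# ---- candidate genes ---------------------------------------------------------

#' Nearest candidate genes around a probe
#'
#' Returns up to `n_per_side` nearest TSSs upstream and downstream of the
#' probe on its chromosome. The signed distance is `tss - pos` (negative =
#' upstream of the probe); ranks 1..2*n_per_side order candidates by absolute
#' distance, ties broken by gene id.
#'
#' @param probe one-row data.frame (or list) with `id`, `chrom`, `pos`.
#' @param genes gene models data.frame.
#' @param n_per_side genes per side (default 10).
#' @return data.frame with `probe_id`, `gene_id`, `signed_distance`, `side`,
#'   `rank`; zero rows (with a warning) if the chromosome is unannotated.
#' @export
adjacent_genes <- function(probe, genes, n_per_side = 10) {
  g <- genes[genes$chrom == probe$chrom, , drop = FALSE]
  empty <- data.frame(probe_id = character(), gene_id = character(),
                      signed_distance = integer(), side = character(),
                      rank = integer(), stringsAsFactors = FALSE)
  if (!nrow(g)) {
    warning(sprintf("probe %s: chromosome %s has no annotated genes",
                    probe$id, probe$chrom))
    return(empty)
  }
  d <- g$tss - probe$pos
  side <- ifelse(d < 0, "upstream", "downstream")
  take <- function(s) {
    i <- which(side == s)
    i[order(abs(d[i]), g$gene_id[i])][seq_len(min(n_per_side, length(i)))]
  }
  sel <- c(take("upstream"), take("downstream"))
  if (!length(sel)) return(empty)
  out <- data.frame(probe_id = probe$id, gene_id = g$gene_id[sel],
                    signed_distance = as.integer(d[sel]), side = side[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(abs(out$signed_distance), out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# ---- permutation empirical p -------------------------------------------------

# Precompute M/U extreme-group sample indices for a set of probes.
# Returns list of lists of integer column indices into beta.
pool_groups <- function(beta, probe_ids, fraction = 0.2) {
  ids <- colnames(beta)
  lapply(probe_ids, function(p) {
    v <- beta[p, ]
    list(M = extreme_indices(v, fraction, "high", ids = ids),
         U = extreme_indices(v, fraction, "low", ids = ids))
  })
}

# p-values of the M<U expression test for one gene against every probe in
# `groups` (as from pool_groups). Vectorised over probes when group sizes are
# uniform and expression is complete; falls back to a loop otherwise.
gene_perm_pvalues <- function(gene_expr, groups, exact_max = 12L) {
  kM <- lengths(lapply(groups, `[[`, "M"))
  kU <- lengths(lapply(groups, `[[`, "U"))
  if (length(unique(kM)) == 1 && length(unique(kU)) == 1 &&
      !anyNA(gene_expr) && (kM[1] + kU[1]) > exact_max) {
    k <- kM[1]; n <- kU[1]; N <- k + n
    idx <- vapply(groups, function(g) c(g$M, g$U), integer(N))
    V <- matrix(gene_expr[idx], nrow = N)
    R <- apply(V, 2, rank)
    u <- colSums(R[seq_len(k), , drop = FALSE]) - k * (k + 1) / 2
    tiecor <- apply(V, 2, function(v) {
      tb <- tabulate(match(v, unique(v))); sum(tb^3 - tb)
    })
    sig2 <- k * n / 12 * ((N + 1) - tiecor / (N * (N - 1)))
    p <- ifelse(sig2 <= 0, 0.5,
                stats::pnorm((u - k * n / 2 + 0.5) / sqrt(pmax(sig2, 0))))
    return(as.numeric(p))
  }
  vapply(groups, function(g) {
    xM <- gene_expr[g$M]; xU <- gene_expr[g$U]
    xM <- xM[!is.na(xM)]; xU <- xU[!is.na(xU)]
    if (length(xM) < 2 || length(xU) < 2) return(NA_real_)
    u_test(xM, xU, exact_max = exact_max)
  }, numeric(1))
}

#' Permutation empirical p-value for a probe-gene pair
#'
#' Holds the gene constant and repeats the same one-sided U test with
#' `nperm` random probes drawn from the distal non-enhancer pool, yielding
#' permutation p-values Pp. The empirical p-value adds a pseudo-count of 1:
#' `p_e = (num(Pp <= p_r) + 1) / (nperm + 1)`.
#'
#' Sampling is without replacement when the pool holds at least `nperm`
#' probes, otherwise with replacement (with a message).
#'
#' @param p_r raw p-value of the tested pair.
#' @param probe_pool character vector of distal non-enhancer probe ids
#'   present in `beta` (ignored if `perm_p` is supplied).
#' @param beta beta matrix covering the pool probes.
#' @param gene_expr named expression vector for the pair's gene.
#' @param nperm number of permutation probes (default 10000).
#' @param seed integer seed (required when sampling).
#' @param fraction extreme-group proportion.
#' @param perm_p optional precomputed permutation p-values; when given the
#'   formula is applied directly with `nperm = length(perm_p)`.
#' @return empirical p-value in `[1/(nperm+1), 1]`.
#' @export
empirical_pvalue <- function(p_r, probe_pool = NULL, beta = NULL,
                             gene_expr = NULL, nperm = 10000, seed = NULL,
                             fraction = 0.2, perm_p = NULL) {
  if (is.null(perm_p)) {
    if (is.null(probe_pool) || !length(probe_pool))
      stop("empty permutation probe pool", call. = FALSE)
    if (is.null(seed)) stop("seed is required", call. = FALSE)
    set.seed(seed)
    drawn <- if (length(probe_pool) >= nperm) {
      sample(probe_pool, nperm)
    } else {
      message(sprintf(
        "pool (%d) smaller than nperm (%d): sampling with replacement",
        length(probe_pool), nperm))
      sample(probe_pool, nperm, replace = TRUE)
    }
    groups <- pool_groups(beta, drawn, fraction)
    perm_p <- gene_perm_pvalues(gene_expr, groups)
    perm_p <- perm_p[!is.na(perm_p)]
  }
  (sum(perm_p <= p_r) + 1) / (length(perm_p) + 1)
}

# ---- pair discovery ----------------------------------------------------------

#' Link differentially methylated probes to target genes
#'
#' For each called probe that passes the variability filter, tests the 10
#' nearest genes on each side ([pair_utest()]) and corrects each raw p-value
#' with the permutation empirical p-value over the distal non-enhancer pool.
#' Pairs with `p_e < pe_max` are reported.
#'
#' @param diff_calls data.frame from [call_diff_probes()].
#' @param universe a `probe_universe`.
#' @param beta,expr sample-matched beta and expression matrices.
#' @param genes gene models data.frame.
#' @param sheet sample sheet (used for the variability filter population:
#'   all matched samples).
#' @param pe_max empirical-p threshold (default 0.001).
#' @param nperm permutation count (default 10000).
#' @param seed integer seed for permutation draws (required).
#' @param fraction extreme-group proportion.
#' @param n_per_side candidate genes per side.
#' @param var_min_frac,var_beta variability-filter parameters.
#' @param perm_scope `"pair"` (each pair draws its own permutation probes) or
#'   `"probe"` (the 20 genes of one probe share a draw).
#' @return data.frame of pairs sorted by (probe, p_e): `probe_id`, `gene_id`,
#'   `distance`, `gene_rank`, `p_r`, `p_e`. All tested candidates are
#'   attached as attribute `"tested"`.
#' @export
find_pairs <- function(diff_calls, universe, beta, expr, genes, sheet,
                       pe_max = 0.001, nperm = 10000, seed,
                       fraction = 0.2, n_per_side = 10,
                       var_min_frac = 0.05, var_beta = 0.3,
                       perm_scope = c("pair", "probe")) {
  perm_scope <- match.arg(perm_scope)
  stopifnot(!missing(seed))
  pool <- intersect(universe$distal_nonenhancer, rownames(beta))
  if (!length(pool)) stop("empty permutation probe pool", call. = FALSE)
  with_repl <- length(pool) < nperm
  if (with_repl)
    message(sprintf(
      "pool (%d) smaller than nperm (%d): sampling with replacement",
      length(pool), nperm))
  probes_called <- sort(unique(diff_calls$probe_id))
  manifest <- universe$probes
  direction <- if (nrow(diff_calls)) diff_calls$direction[1] else "hypo"

  # permutation p-values for every pool probe are deterministic per gene;
  # cache them and let each pair sample indices from the cache
  groups <- pool_groups(beta, pool, fraction)
  gene_cache <- new.env(parent = emptyenv())
  gene_pp <- function(gid) {
    if (!is.null(gene_cache[[gid]])) return(gene_cache[[gid]])
    pp <- gene_perm_pvalues(expr[gid, ], groups)
    gene_cache[[gid]] <- pp
    pp
  }

  set.seed(seed)
  rows <- list()
  for (pid in probes_called) {
    pb <- beta[pid, ]
    if (!variability_filter(pb, var_min_frac, var_beta, direction)) next
    pr_row <- manifest[manifest$id == pid, , drop = FALSE]
    if (!nrow(pr_row)) next
    cand <- adjacent_genes(pr_row[1, ], genes, n_per_side)
    cand <- cand[cand$gene_id %in% rownames(expr), , drop = FALSE]
    if (!nrow(cand)) next
    if (perm_scope == "probe")
      probe_draw <- sample(length(pool), nperm, replace = with_repl)
    for (j in seq_len(nrow(cand))) {
      gid <- cand$gene_id[j]
      p_r <- pair_utest(pb, expr[gid, ], fraction)
      if (is.null(p_r)) {
        message(sprintf("pair %s-%s skipped: degenerate groups", pid, gid))
        next
      }
      idx <- if (perm_scope == "probe") probe_draw
             else sample(length(pool), nperm, replace = with_repl)
      pp <- gene_pp(gid)[idx]
      pp <- pp[!is.na(pp)]
      p_e <- (sum(pp <= p_r) + 1) / (length(pp) + 1)
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = pid, gene_id = gid,
        distance = cand$signed_distance[j], gene_rank = cand$rank[j],
        p_r = p_r, p_e = p_e, stringsAsFactors = FALSE)
    }
  }
  tested <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probe_id = character(), gene_id = character(),
               distance = integer(), gene_rank = integer(),
               p_r = numeric(), p_e = numeric(), stringsAsFactors = FALSE)
  out <- tested[tested$p_e < pe_max, , drop = FALSE]
  out <- out[order(out$probe_id, out$p_e, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tested") <- tested
  out
}

# ---- clustering --------------------------------------------------------------

#' Cluster probes within a base-pair gap into enhancer regions
#'
#' Single-linkage chaining: probes sorted by position on a chromosome join
#' one cluster while consecutive positions are at most `gap` apart.
#'
#' @param probes data.frame with `id`, `chrom`, `pos`.
#' @param gap maximum distance between consecutive member probes (default
#'   500 bp).
#' @return data.frame with `cluster_id`, `chrom`, `start`, `end` (1-based
#'   positions of the outermost probes), `n_probes`, `probe_ids`
#'   (comma-separated).
#' @export
cluster_probes <- function(probes, gap = 500) {
  out <- list()
  cid <- 0L
  for (ch in sort(unique(probes$chrom))) {
    p <- probes[probes$chrom == ch, , drop = FALSE]
    p <- p[order(p$pos, p$id), , drop = FALSE]
    brk <- c(0L, which(diff(p$pos) > gap), nrow(p))
    for (b in seq_len(length(brk) - 1L)) {
      i <- (brk[b] + 1L):brk[b + 1L]
      cid <- cid + 1L
      out[[cid]] <- data.frame(
        cluster_id = sprintf("cluster_%04d", cid), chrom = ch,
        start = min(p$pos[i]), end = max(p$pos[i]),
        n_probes = length(i),
        probe_ids = paste(p$id[i], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(cluster_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_probes = integer(), probe_ids = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# ---- characterization --------------------------------------------------------

#' Probe-gene distance histogram with a randomized null band
#'
#' Tabulates the proportion of pairs per absolute-distance bin and compares
#' it to a null built by repeatedly drawing `n_probes` random distal probes,
#' pairing each with one of its 20 adjacent genes chosen uniformly, over
#' `n_datasets` datasets; the band is mean +/- 1.96 * SD per bin.
#'
#' @param pairs data.frame from [find_pairs()].
#' @param distal_ids distal probe ids forming the null pool.
#' @param probes probe manifest.
#' @param genes gene models.
#' @param binwidth histogram bin width in bp (e.g. 50000 or 200000).
#' @param n_bins number of bins; the last bin is open-ended.
#' @param n_datasets number of null datasets (default 1000).
#' @param n_probes probes per null dataset (default 1000).
#' @param seed integer seed.
#' @param n_per_side candidate genes per side.
#' @return data.frame per bin: `bin_lo`, `bin_hi`, `observed`, `null_mean`,
#'   `null_lo`, `null_hi`.
#' @export
distance_null_histogram <- function(pairs, distal_ids, probes, genes,
                                    binwidth = 50000, n_bins = 20,
                                    n_datasets = 1000, n_probes = 1000,
                                    seed, n_per_side = 10) {
  stopifnot(nrow(pairs) > 0, !missing(seed))
  edges <- c(seq(0, binwidth * (n_bins - 1), by = binwidth), Inf)
  binprop <- function(d) {
    h <- findInterval(abs(d), edges, rightmost.closed = FALSE)
    tabulate(h, nbins = n_bins) / length(d)
  }
  obs <- binprop(pairs$distance)
  pool <- probes[probes$id %in% distal_ids, , drop = FALSE]
  set.seed(seed)
  # candidate distances are fixed per probe: precompute for the pool once
  cand <- lapply(seq_len(nrow(pool)), function(i)
    suppressWarnings(adjacent_genes(pool[i, ], genes, n_per_side))$signed_distance)
  names(cand) <- pool$id
  cand <- cand[lengths(cand) > 0]
  nullp <- matrix(NA_real_, nrow = n_datasets, ncol = n_bins)
  for (s in seq_len(n_datasets)) {
    pi <- sample(length(cand), n_probes, replace = length(cand) < n_probes)
    d <- vapply(cand[pi], function(ds) ds[sample.int(length(ds), 1)],
                numeric(1))
    nullp[s, ] <- binprop(d)
  }
  mu <- colMeans(nullp); sd <- apply(nullp, 2, stats::sd)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             observed = obs, null_mean = mu,
             null_lo = mu - 1.96 * sd, null_hi = mu + 1.96 * sd)
}

#' Gene-rank profile of one-to-one pairs
#'
#' Drops probes linked to more than one gene and genes linked by more than
#' one probe, then tabulates the proportion of surviving pairs at each
#' candidate gene rank.
#'
#' @param pairs data.frame from [find_pairs()].
#' @param n_ranks number of ranks to report (default 20).
#' @return numeric vector of proportions, names `rank1`..`rankN`.
#' @export
nearest_rank_profile <- function(pairs, n_ranks = 20) {
  keep <- !(pairs$probe_id %in% pairs$probe_id[duplicated(pairs$probe_id)]) &
          !(pairs$gene_id %in% pairs$gene_id[duplicated(pairs$gene_id)])
  p <- pairs[keep, , drop = FALSE]
  counts <- tabulate(p$gene_rank, nbins = n_ranks)
  prop <- if (nrow(p)) counts / nrow(p) else rep(0, n_ranks)
  names(prop) <- paste0("rank", seq_len(n_ranks))
  prop
}

#' Overlap of probe-gene pairs with chromatin loops
#'
#' A pair overlaps a loop iff the probe position falls inside one anchor and
#' the gene TSS inside the other, in either orientation. The null preserves
#' the per-probe link-count multiset: each random dataset draws as many
#' random distal enhancer probes as there are true probes, and gives the
#' i-th random probe exactly as many links (to randomly chosen adjacent
#' genes) as the i-th true probe has.
#'
#' @param pairs data.frame from [find_pairs()].
#' @param loops data.frame from [read_loops()].
#' @param enhancer_ids distal enhancer probe ids (null pool).
#' @param probes probe manifest.
#' @param genes gene models.
#' @param n_random number of random datasets (default 100).
#' @param seed integer seed.
#' @param n_per_side candidate genes per side.
#' @return list with `observed`, `null_mean`, `null_sd`, `fold`, `ci_lo`,
#'   `ci_hi` (fold is NA when the loop set is empty).
#' @export
loop_overlap_enrichment <- function(pairs, loops, enhancer_ids, probes,
                                    genes, n_random = 100, seed,
                                    n_per_side = 10) {
  stopifnot(!missing(seed))
  if (is.null(loops) || !nrow(loops))
    return(list(observed = NA_integer_, null_mean = NA_real_,
                null_sd = NA_real_, fold = NA_real_,
                ci_lo = NA_real_, ci_hi = NA_real_))
  anchorA <- GenomicRanges::GRanges(
    loops$chromA, IRanges::IRanges(loops$startA + 1L, loops$endA))
  anchorB <- GenomicRanges::GRanges(
    loops$chromB, IRanges::IRanges(loops$startB + 1L, loops$endB))
  count_overlaps <- function(pid, gid) {
    pp <- probes[match(pid, probes$id), ]
    gg <- genes[match(gid, genes$gene_id), ]
    pg <- GenomicRanges::GRanges(pp$chrom, IRanges::IRanges(pp$pos, width = 1L))
    tg <- GenomicRanges::GRanges(gg$chrom, IRanges::IRanges(gg$tss, width = 1L))
    # disjoint seqlevels are expected (loops may cover other chromosomes)
    ov <- function(q, s) suppressWarnings(GenomicRanges::findOverlaps(q, s))
    pa <- ov(pg, anchorA)
    gb <- ov(tg, anchorB)
    pb <- ov(pg, anchorB)
    ga <- ov(tg, anchorA)
    hit <- logical(length(pid))
    for (i in seq_along(pid)) {
      la <- S4Vectors::subjectHits(pa)[S4Vectors::queryHits(pa) == i]
      lb <- S4Vectors::subjectHits(gb)[S4Vectors::queryHits(gb) == i]
      if (length(intersect(la, lb))) { hit[i] <- TRUE; next }
      la <- S4Vectors::subjectHits(pb)[S4Vectors::queryHits(pb) == i]
      lb <- S4Vectors::subjectHits(ga)[S4Vectors::queryHits(ga) == i]
      if (length(intersect(la, lb))) hit[i] <- TRUE
    }
    sum(hit)
  }
  observed <- count_overlaps(pairs$probe_id, pairs$gene_id)
  link_counts <- table(pairs$probe_id)  # per-probe multiset to preserve
  pool <- probes[probes$id %in% enhancer_ids, , drop = FALSE]
  set.seed(seed)
  rand_counts <- vapply(seq_len(n_random), function(s) {
    ridx <- sample(nrow(pool), length(link_counts),
                   replace = nrow(pool) < length(link_counts))
    rp <- character(0); rg <- character(0)
    for (i in seq_along(ridx)) {
      cand <- suppressWarnings(
        adjacent_genes(pool[ridx[i], ], genes, n_per_side))
      if (!nrow(cand)) next
      k <- min(as.integer(link_counts[i]), nrow(cand))
      pick <- sample.int(nrow(cand), k)
      rp <- c(rp, rep(pool$id[ridx[i]], k))
      rg <- c(rg, cand$gene_id[pick])
    }
    count_overlaps(rp, rg)
  }, numeric(1))
  mu <- mean(rand_counts); sdv <- stats::sd(rand_counts)
  list(observed = observed, null_mean = mu, null_sd = sdv,
       fold = if (mu > 0) observed / mu else NA_real_,
       ci_lo = mu - 1.96 * sdv, ci_hi = mu + 1.96 * sdv,
       random_counts = rand_counts)
}
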