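# Upstream regulator inference: for each enriched motif, compare TF
# expression between the samples with the highest and lowest average
# methylation over motif-adjacent paired probes, and rank TFs by how
# strongly their expression anti-correlates with that methylation.

#' Per-sample methylation profile of a motif
#'
#' Averages beta values over the paired probes that carry at least one
#' occurrence of the motif (missing betas excluded per sample).
#'
#' @param motif_id motif to profile.
#' @param hits hit data.frame from [scan_windows()].
#' @param paired_probes probe ids of the gene-linked (paired) set.
#' @param beta beta matrix.
#' @return list with `motif_id`, `probe_ids`, `profile` (named per-sample
#'   mean beta), or NULL when no paired probe has a hit for the motif.
#' @export
motif_profile <- function(motif_id, hits, paired_probes, beta) {
  with_hit <- unique(hits$probe_id[hits$motif_id == motif_id])
  use <- intersect(intersect(paired_probes, with_hit), rownames(beta))
  if (!length(use)) {
    message(sprintf("motif %s: no paired probe with a hit; skipped", motif_id))
    return(NULL)
  }
  prof <- colMeans(beta[use, , drop = FALSE], na.rm = TRUE)
  if (anyNA(prof))
    stop(sprintf("motif %s: some sample has no non-missing beta", motif_id),
         call. = FALSE)
  list(motif_id = motif_id, probe_ids = use, profile = prof)
}

#' Rank transcription factors against a motif methylation profile
#'
#' Splits samples into the M group (highest average motif methylation,
#' `fraction` of samples) and U group (lowest), then tests each TF with the
#' one-sided Mann-Whitney test (alternative: expression in M below U). TFs
#' are ranked by -log10(p), ties broken by gene id; the top `top` fraction
#' (ceiling) are candidate upstream regulators.
#'
#' @param profile list from [motif_profile()] (or any named per-sample
#'   numeric vector supplied as `profile$profile`).
#' @param expr expression matrix covering the same samples.
#' @param tf_ids TF gene ids; ids absent from `expr` are skipped with a
#'   message.
#' @param fraction extreme-group proportion (default 0.2).
#' @param top top fraction considered candidate regulators (default 0.05).
#' @return data.frame sorted by rank: `motif_id`, `tf_gene_id`, `p_r`,
#'   `rank`, `in_top`.
#' @export
rank_tfs <- function(profile, expr, tf_ids, fraction = 0.2, top = 0.05) {
  prof <- profile$profile
  samples <- intersect(names(prof), colnames(expr))
  if (length(samples) < length(prof))
    prof <- prof[samples]
  iM <- extreme_indices(prof, fraction, "high")
  iU <- extreme_indices(prof, fraction, "low")
  if (length(iM) < 2 || length(iU) < 2)
    stop("degenerate extreme groups for motif profile", call. = FALSE)
  missing_tfs <- setdiff(tf_ids, rownames(expr))
  if (length(missing_tfs))
    message(sprintf("%d TF(s) absent from expression matrix; skipped",
                    length(missing_tfs)))
  tfs <- intersect(tf_ids, rownames(expr))
  sM <- names(prof)[iM]; sU <- names(prof)[iU]
  p <- vapply(tfs, function(tf) {
    xM <- expr[tf, sM]; xU <- expr[tf, sU]
    xM <- xM[!is.na(xM)]; xU <- xU[!is.na(xU)]
    if (length(xM) < 2 || length(xU) < 2) return(NA_real_)
    u_test(xM, xU)
  }, numeric(1))
  ok <- !is.na(p)
  tfs <- tfs[ok]; p <- p[ok]
  o <- order(p, tfs)
  n_top <- ceiling(top * length(tfs))
  out <- data.frame(motif_id = profile$motif_id %||% NA_character_,
                    tf_gene_id = tfs[o], p_r = p[o],
                    rank = seq_along(tfs),
                    in_top = seq_along(tfs) <= n_top,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve the likely upstream regulator using the motif's binding family
#'
#' For each motif's TF ranking, reports the top three TFs overall plus every
#' member of the motif's DNA-binding family with its rank; the best-ranked
#' family member is flagged as the candidate regulator iff it falls in the
#' top 5 % set.
#'
#' @param assocs data.frame from [rank_tfs()] (one motif or several stacked).
#' @param family_map named list: motif_id -> character vector of family
#'   member gene ids.
#' @return data.frame, one row per motif: `motif_id`, `top3` (comma
#'   separated), `family_members`, `best_family_member`,
#'   `best_family_rank`, `flagged` (logical).
#' @export
resolve_family <- function(assocs, family_map) {
  motifs <- unique(assocs$motif_id)
  rows <- lapply(motifs, function(mid) {
    a <- assocs[assocs$motif_id == mid, , drop = FALSE]
    a <- a[order(a$rank), , drop = FALSE]
    top3 <- paste(utils::head(a$tf_gene_id, 3), collapse = ",")
    fam <- family_map[[mid]]
    if (is.null(fam) || !length(fam))
      return(data.frame(motif_id = mid, top3 = top3,
                        family_members = "", best_family_member = NA_character_,
                        best_family_rank = NA_integer_, flagged = FALSE,
                        stringsAsFactors = FALSE))
    af <- a[a$tf_gene_id %in% fam, , drop = FALSE]
    if (!nrow(af))
      return(data.frame(motif_id = mid, top3 = top3,
                        family_members = paste(fam, collapse = ","),
                        best_family_member = NA_character_,
                        best_family_rank = NA_integer_, flagged = FALSE,
                        stringsAsFactors = FALSE))
    best <- af[1, ]
    data.frame(motif_id = mid, top3 = top3,
               family_members = paste(sprintf("%s(rank %d)", af$tf_gene_id,
                                              af$rank), collapse = ","),
               best_family_member = best$tf_gene_id,
               best_family_rank = best$rank,
               flagged = isTRUE(best$in_top),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
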