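# Cancer-specific differential methylation: extreme-quintile Welch t-tests on
# tumor vs normal betas, Benjamini-Hochberg adjusted, with an effect-size
# floor on delta = mu_normal - mu_tumor.

#' Indices of the extreme (lowest or highest) fraction of values
#'
#' Selects `k = max(1, floor(fraction * n_nonmissing))` indices of the k
#' smallest (`side = "low"`) or largest (`side = "high"`) non-missing values.
#' Ties are broken by the lexicographic order of `ids` (sample ids), making
#' the selection deterministic.
#'
#' @param values numeric vector, may contain NA.
#' @param fraction proportion in (0, 0.5].
#' @param side `"low"` or `"high"`.
#' @param ids optional character vector of the same length used for
#'   tie-breaking; defaults to names(values) or the index as character.
#' @return integer vector of selected indices into `values`.
#' @export
extreme_indices <- function(values, fraction = 0.2, side = c("low", "high"),
                            ids = NULL) {
  side <- match.arg(side)
  if (is.null(ids)) ids <- names(values)
  if (is.null(ids)) ids <- as.character(seq_along(values))
  ok <- which(!is.na(values))
  if (!length(ok)) stop("all values missing", call. = FALSE)
  k <- max(1L, floor(fraction * length(ok)))
  v <- values[ok]
  o <- if (side == "low") order(v, ids[ok]) else order(-v, ids[ok])
  unname(ok[o[seq_len(k)]])
}

#' One-tailed Welch t-test on extreme methylation quintiles
#'
#' Compares the extreme groups of tumor and normal betas: for `"hypo"` the
#' lower quintiles with alternative mu_tumor < mu_normal, for `"hyper"` the
#' upper quintiles with alternative mu_tumor > mu_normal. Group size follows
#' the [extreme_indices()] floor-with-clamp rule.
#'
#' @param tumor_betas named numeric vector of tumor betas (may contain NA).
#' @param normal_betas named numeric vector of normal betas.
#' @param direction `"hypo"` or `"hyper"`.
#' @param fraction extreme-group proportion (default 0.2, a quintile).
#' @param pooled_var use the pooled-variance t-test instead of Welch.
#' @return list with `p_raw`, `mu_tumor`, `mu_normal`, `delta`
#'   (= mu_normal - mu_tumor), and `n_tumor`, `n_normal` group sizes, or NULL
#'   if either extreme group has fewer than 2 usable samples.
#' @export
quintile_ttest <- function(tumor_betas, normal_betas,
                           direction = c("hypo", "hyper"), fraction = 0.2,
                           pooled_var = FALSE) {
  direction <- match.arg(direction)
  side <- if (direction == "hypo") "low" else "high"
  it <- try(extreme_indices(tumor_betas, fraction, side), silent = TRUE)
  im <- try(extreme_indices(normal_betas, fraction, side), silent = TRUE)
  if (inherits(it, "try-error") || inherits(im, "try-error")) return(NULL)
  gt <- tumor_betas[it]
  gn <- normal_betas[im]
  if (length(gt) < 2 || length(gn) < 2) return(NULL)
  mu_t <- mean(gt); mu_n <- mean(gn)
  alt <- if (direction == "hypo") "less" else "greater"
  if (stats::sd(gt) == 0 && stats::sd(gn) == 0) {
    # degenerate: no variance in either group
    p <- if (mu_t == mu_n) 0.5
         else if ((direction == "hypo") == (mu_t < mu_n)) 0 else 1
  } else {
    p <- stats::t.test(gt, gn, alternative = alt,
                       var.equal = pooled_var)$p.value
  }
  list(p_raw = p, mu_tumor = mu_t, mu_normal = mu_n, delta = mu_n - mu_t,
       n_tumor = length(gt), n_normal = length(gn))
}

#' Call differentially methylated probes
#'
#' Runs [quintile_ttest()] for every probe of a beta matrix (typically
#' restricted to enhancer probes), adjusts raw p-values with
#' Benjamini-Hochberg across all tested probes of the cohort, and returns the
#' probes passing both the adjusted-p and the |delta| thresholds.
#'
#' @param beta probes x samples beta matrix.
#' @param sheet sample sheet data.frame covering the matrix columns.
#' @param direction `"hypo"` or `"hyper"`.
#' @param fraction extreme-group proportion (default 0.2).
#' @param p_adj_max adjusted-p threshold (default 0.01).
#' @param delta_min minimum |mu_normal - mu_tumor| (default 0.3).
#' @param pooled_var passed to [quintile_ttest()].
#' @return data.frame of calls sorted by `p_adj` then probe id, with columns
#'   `probe_id`, `direction`, `mu_tumor`, `mu_normal`, `delta`, `p_raw`,
#'   `p_adj`. The full tested table (before thresholding) is attached as
#'   attribute `"tested"`.
#' @export
call_diff_probes <- function(beta, sheet, direction = c("hypo", "hyper"),
                             fraction = 0.2, p_adj_max = 0.01,
                             delta_min = 0.3, pooled_var = FALSE) {
  direction <- match.arg(direction)
  tum <- intersect(colnames(beta), sheet$sample_id[sheet$group == "tumor"])
  nor <- intersect(colnames(beta), sheet$sample_id[sheet$group == "normal"])
  if (!length(tum) || !length(nor))
    stop("cohort must contain both tumor and normal samples", call. = FALSE)
  res <- lapply(rownames(beta), function(pid) {
    r <- quintile_ttest(beta[pid, tum], beta[pid, nor], direction,
                        fraction = fraction, pooled_var = pooled_var)
    if (is.null(r)) {
      message(sprintf("probe %s skipped: degenerate extreme group", pid))
      return(NULL)
    }
    data.frame(probe_id = pid, direction = direction,
               mu_tumor = r$mu_tumor, mu_normal = r$mu_normal,
               delta = r$delta, p_raw = r$p_raw, stringsAsFactors = FALSE)
  })
  tested <- do.call(rbind, res)
  if (is.null(tested) || !nrow(tested)) {
    out <- data.frame(probe_id = character(), direction = character(),
                      mu_tumor = numeric(), mu_normal = numeric(),
                      delta = numeric(), p_raw = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE)
    attr(out, "tested") <- out
    return(out)
  }
  tested$p_adj <- stats::p.adjust(tested$p_raw, method = "BH")
  pass_delta <- if (direction == "hypo") tested$delta > delta_min
                else -tested$delta > delta_min
  out <- tested[tested$p_adj < p_adj_max & pass_delta, , drop = FALSE]
  out <- out[order(out$p_adj, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tested") <- tested
  out
}
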