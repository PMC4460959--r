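# End-to-end orchestration: probe universe -> differential methylation ->
# probe-gene pairs -> clusters -> motif scan -> enrichment -> TF ranking,
# with one config object holding every threshold and a provenance stamp
# (package version, seed, config hash) on all outputs.

#' Pipeline configuration (all thresholds in one place)
#'
#' Defaults are the method's standard operating point: 2 kb TSS distance for
#' distal probes, extreme quintiles (0.2), BH-adjusted p below 0.01 with
#' |delta| above 0.3 for differential methylation, a 5 % / beta 0.3
#' variability filter, 10 candidate genes per side, 10,000 permutations with
#' empirical p below 0.001 for pairs, +/-100 bp motif windows scanned at
#' p below 1e-4, enrichment requiring the 95 % lower CI of the OR above 1.1
#' and at least 10 in-set occurrences, top 5 % TF ranking, and 500 bp probe
#' clustering.
#'
#' @param ... overrides of the defaults listed above.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    tss_min_dist = 2000,
    enhancer_states = c("EnhG1", "EnhG2", "EnhA1", "EnhA2"),
    extreme_fraction = 0.2,
    padj_max = 0.01,
    delta_min = 0.3,
    variability_min_frac = 0.05,
    variability_beta = 0.3,
    n_adjacent_per_side = 10,
    nperm = 10000,
    pe_max = 0.001,
    scan_window = 100,
    scan_pmax = 1e-4,
    or_floor = 1.1,
    min_occurrences = 10,
    ci_z = 1.96,
    tf_top = 0.05,
    cluster_gap = 500,
    perm_scope = "pair",
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' FNV-1a hash of a configuration (provenance stamp)
#' @param cfg any R object; hashed over its canonical deparse.
#' @return 8-hex-digit character scalar.
#' @export
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(unclass(cfg)))]), collapse = "")
  # 32-bit FNV-1a in double arithmetic (kept exact by 16-bit split multiply)
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 65536
    h <- (h - low) + bitwXor(as.integer(low), as.integer(b))
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full enhancer-linking pipeline
#'
#' Stages: build the probe universe, match the cohort samples, call
#' differentially methylated enhancer probes, link them to target genes,
#' cluster called probes, scan probe windows for motifs, test motif
#' enrichment of the paired set, and rank upstream TFs per enriched motif.
#' A stage failure aborts with an error naming the stage.
#'
#' @param inputs either a `sim_cohort` or a named list with `probes`,
#'   `enhancers`, `genome`, `beta`, `expr`, `sheet`, `genes`, `pwms`,
#'   `tf_ids` and optionally `family_map` (in-memory objects, or for the
#'   file-based interface paths readable by the package's readers).
#' @param cfg a [pipeline_config()].
#' @param direction `"hypo"`, `"hyper"` or `"both"`.
#' @return object of class `enhancerlink_result`: list with `universe`,
#'   per-direction `diff_calls`, `pairs`, `clusters`, plus `hits`,
#'   `enrichment`, `tf_ranks`, `tf_report`, `config`, `config_hash`,
#'   `version`.
#' @export
run_pipeline <- function(inputs, cfg = pipeline_config(),
                         direction = c("hypo", "hyper", "both")) {
  direction <- match.arg(direction)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  inp <- resolve_inputs(inputs)

  enh <- inp$enhancers
  if (!is.null(cfg$enhancer_states))
    enh <- enh[enh$label %in% cfg$enhancer_states, , drop = FALSE]
  universe <- stage("select-probes",
    build_probe_universe(inp$probes, inp$genes, enh,
                         min_dist = cfg$tss_min_dist))
  cohort <- stage("match-cohort",
    match_cohort(inp$beta, inp$expr, inp$sheet))
  enh_beta <- cohort$beta[intersect(rownames(cohort$beta),
                                    universe$distal_enhancer), , drop = FALSE]

  dirs <- if (direction == "both") c("hypo", "hyper") else direction
  diff_calls <- list(); pairs <- list(); clusters <- list()
  for (d in dirs) {
    diff_calls[[d]] <- stage("diff-meth",
      call_diff_probes(enh_beta, cohort$sheet, d,
                       fraction = cfg$extreme_fraction,
                       p_adj_max = cfg$padj_max, delta_min = cfg$delta_min))
    pairs[[d]] <- stage("link",
      find_pairs(diff_calls[[d]], universe, cohort$beta, cohort$expr,
                 inp$genes, cohort$sheet, pe_max = cfg$pe_max,
                 nperm = cfg$nperm, seed = cfg$seed,
                 fraction = cfg$extreme_fraction,
                 n_per_side = cfg$n_adjacent_per_side,
                 var_min_frac = cfg$variability_min_frac,
                 var_beta = cfg$variability_beta,
                 perm_scope = cfg$perm_scope))
    called <- inp$probes[inp$probes$id %in% diff_calls[[d]]$probe_id, ,
                         drop = FALSE]
    clusters[[d]] <- stage("cluster", cluster_probes(called,
                                                     gap = cfg$cluster_gap))
  }

  paired_ids <- sort(unique(unlist(lapply(pairs, function(p) p$probe_id))))
  hits <- NULL; enrichment <- NULL; tf_ranks <- NULL; tf_report <- NULL
  if (is.null(inp$genome) || is.null(inp$pwms)) {
    message("no genome/motif inputs: stopping after pairing")
  } else if (!length(paired_ids)) {
    message("no probe-gene pairs: motif stages skipped")
  } else {
    scan_set <- inp$probes[inp$probes$id %in% universe$distal_enhancer, ,
                           drop = FALSE]
    hits <- stage("scan",
      scan_windows(scan_set, inp$genome, inp$pwms,
                   window = cfg$scan_window, p_max = cfg$scan_pmax))
    enrichment <- stage("enrich",
      motif_enrichment(paired_ids, universe$distal_enhancer, hits,
                       or_floor = cfg$or_floor,
                       min_occurrences = cfg$min_occurrences, z = cfg$ci_z))
    enriched <- enrichment$motif_id[enrichment$enriched]
    if (length(enriched) && !is.null(inp$tf_ids)) {
      tf_ranks <- stage("tf-rank", do.call(rbind, Filter(Negate(is.null),
        lapply(enriched, function(mid) {
          prof <- motif_profile(mid, hits, paired_ids, cohort$beta)
          if (is.null(prof)) return(NULL)
          rank_tfs(prof, cohort$expr, inp$tf_ids,
                   fraction = cfg$extreme_fraction, top = cfg$tf_top)
        }))))
      if (!is.null(tf_ranks) && !is.null(inp$family_map))
        tf_report <- stage("tf-rank",
                           resolve_family(tf_ranks, inp$family_map))
    }
  }

  structure(list(universe = universe, diff_calls = diff_calls,
                 pairs = pairs, clusters = clusters, hits = hits,
                 enrichment = enrichment, tf_ranks = tf_ranks,
                 tf_report = tf_report, config = cfg,
                 config_hash = config_hash(cfg),
                 version = as.character(utils::packageVersion("enhancerlink"))),
            class = "enhancerlink_result")
}

# accept a sim_cohort, a list of in-memory objects, or a list of file paths
resolve_inputs <- function(inputs) {
  if (inherits(inputs, "sim_cohort")) return(inputs)
  stopifnot(is.list(inputs))
  inp <- inputs
  if (is.character(inp$probes)) inp$probes <- read_probe_manifest(inp$probes)
  if (is.character(inp$enhancers)) inp$enhancers <- read_state_bed(inp$enhancers)
  if (is.character(inp$beta)) inp$beta <- read_matrix(inp$beta, "beta")
  if (is.character(inp$expr)) inp$expr <- read_matrix(inp$expr, "expression")
  if (is.character(inp$sheet)) inp$sheet <- read_sample_sheet(inp$sheet)
  if (is.character(inp$genes)) inp$genes <- read_gene_models(inp$genes)
  if (is.character(inp$pwms)) inp$pwms <- read_meme_motifs(inp$pwms)
  if (is.character(inp$genome)) inp$genome <-
      Biostrings::readDNAStringSet(inp$genome)
  if (is.character(inp$tf_ids) && length(inp$tf_ids) == 1 &&
      file.exists(inp$tf_ids))
    inp$tf_ids <- read_delim_auto(inp$tf_ids)$gene_id
  if (is.character(inp$family_map)) {
    fm <- read_delim_auto(inp$family_map)
    inp$family_map <- split(fm$gene_id, fm$motif_id)
  }
  inp
}

#' @export
print.enhancerlink_result <- function(x, ...) {
  cat(sprintf("enhancerlink result (v%s, config %s, seed %s)\n",
              x$version, x$config_hash, x$config$seed))
  for (d in names(x$diff_calls)) {
    cat(sprintf("  [%s] %d differential probes, %d pairs, %d clusters\n", d,
                nrow(x$diff_calls[[d]]), nrow(x$pairs[[d]]),
                nrow(x$clusters[[d]])))
  }
  if (!is.null(x$enrichment))
    cat(sprintf("  %d motifs tested, %d enriched\n", nrow(x$enrichment),
                sum(x$enrichment$enriched)))
  if (!is.null(x$tf_report)) {
    fl <- x$tf_report[x$tf_report$flagged, , drop = FALSE]
    if (nrow(fl))
      cat(sprintf("  flagged regulator(s): %s\n",
                  paste(sprintf("%s (%s)", fl$best_family_member,
                                fl$motif_id), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.enhancerlink_result <- function(object, ...) {
  print(object)
  if (!is.null(object$enrichment)) {
    cat("\nTop motifs by odds ratio:\n")
    print(utils::head(object$enrichment[, c("motif_id", "a", "c",
                                            "odds_ratio", "lower_ci",
                                            "enriched")], 5))
  }
  invisible(object)
}

#' Write all result tables with provenance headers
#'
#' Every TSV starts with comment lines carrying the package version, seed
#' and config hash, so a rerun with identical inputs and config reproduces
#' byte-identical files.
#'
#' @param result an `enhancerlink_result`.
#' @param dir output directory.
#' @return invisible vector of written paths.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# enhancerlink v%s seed=%s config=%s", result$version,
                 result$config$seed, result$config_hash)
  emit <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(hdr, con)
    close(con)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    path
  }
  paths <- character(0)
  for (d in names(result$diff_calls)) {
    paths <- c(paths, emit(result$diff_calls[[d]],
                           sprintf("diff_meth_%s.tsv", d)),
               emit(result$pairs[[d]], sprintf("pairs_%s.tsv", d)),
               emit(result$clusters[[d]], sprintf("clusters_%s.tsv", d)))
  }
  if (!is.null(result$hits)) paths <- c(paths, emit(result$hits, "hits.tsv"))
  if (!is.null(result$enrichment))
    paths <- c(paths, emit(result$enrichment, "enrichment.tsv"))
  if (!is.null(result$tf_ranks))
    paths <- c(paths, emit(result$tf_ranks, "tf_ranks.tsv"))
  if (!is.null(result$tf_report))
    paths <- c(paths, emit(result$tf_report, "tf_report.tsv"))
  invisible(paths)
}

#' Compare call/pair/gene sets across cohort result bundles
#'
#' Post-hoc tabulation across independently processed cohorts: for each
#' direction, counts in how many cohorts each probe was called and each
#' probe-gene pair was found.
#'
#' @param results named list of `enhancerlink_result` objects.
#' @return list with data.frames `probe_sharing` and `pair_sharing`
#'   (id, n_cohorts, cohorts).
#' @export
compare_cohorts <- function(results) {
  stopifnot(length(names(results)) == length(results))
  tab <- function(get_ids) {
    long <- do.call(rbind, lapply(names(results), function(nm) {
      ids <- get_ids(results[[nm]])
      if (!length(ids)) return(NULL)
      data.frame(id = ids, cohort = nm, stringsAsFactors = FALSE)
    }))
    if (is.null(long))
      return(data.frame(id = character(), n_cohorts = integer(),
                        cohorts = character(), stringsAsFactors = FALSE))
    sp <- split(long$cohort, long$id)
    data.frame(id = names(sp), n_cohorts = lengths(sp),
               cohorts = vapply(sp, paste, character(1), collapse = ","),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(
    probe_sharing = tab(function(r)
      unique(unlist(lapply(r$diff_calls, function(d) d$probe_id)))),
    pair_sharing = tab(function(r)
      unique(unlist(lapply(r$pairs, function(p)
        if (nrow(p)) paste(p$probe_id, p$gene_id, sep = "|") else character(0))))))
}
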