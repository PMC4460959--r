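# Seeded synthetic-cohort generator. Emulates the structure the pipeline
# assumes: tumor-vs-normal beta shifts confined to a molecular-subtype
# subset, target-gene expression anti-correlated with enhancer methylation,
# a consensus motif embedded in driver-probe windows, and a driver TF whose
# expression anti-correlates with driver-probe methylation. Every stage's
# ground truth is recorded in a truth table.

#' Synthetic cohort configuration
#'
#' Defaults describe a mid-sized tumor/normal methylation cohort: 100 tumors
#' of which 40 % belong to the molecular subtype carrying the planted
#' events, 20 normals, 2,000 probes of which 50 are hypomethylated drivers,
#' a planted beta shift of 0.45, and within-group beta dispersion typical of
#' Infinium arrays (concentration 100, SD about 0.04 at beta 0.8).
#'
#' @param n_tumor,n_normal sample counts.
#' @param subtype_fraction fraction of tumors in the planted subtype.
#' @param n_probes total probes; `n_driver_probes` of them are drivers.
#' @param n_driver_probes planted hypomethylated driver probes.
#' @param n_masked probes flagged masked in the manifest.
#' @param enhancer_fraction fraction of probes covered by enhancer states.
#' @param delta_planted beta shift at driver probes in subtype tumors.
#' @param beta_conc Beta-distribution concentration (mean-parameterized).
#' @param link_effect expression slope versus (1 - beta) at planted links.
#' @param noise_sd Gaussian expression noise SD.
#' @param motif_embed_rate probability of embedding the planted motif
#'   consensus in a driver-probe window.
#' @param background_rate embedding probability in other enhancer windows.
#' @param n_decoy_motifs decoy PWMs (never embedded).
#' @param n_decoy_tfs decoy TFs with expression unrelated to methylation.
#' @param tf_effect driver-TF expression slope versus mean driver methylation
#'   (signal-to-noise about 2 with the default `tf_noise_sd`).
#' @param tf_noise_sd Gaussian noise SD on TF expression.
#' @param target_rank candidate-gene rank of each driver's planted target.
#' @param probe_spacing bp between consecutive probes.
#' @param probes_per_chrom probes per synthetic chromosome.
#' @param motif_len planted/decoy motif width.
#' @param window probe flank used for motif embedding (matches scanning).
#' @param seed integer seed (mandatory).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_tumor = 100, n_normal = 20, subtype_fraction = 0.4,
                       n_probes = 2000, n_driver_probes = 50, n_masked = 10,
                       enhancer_fraction = 0.45, delta_planted = 0.45,
                       beta_conc = 100, link_effect = 2, noise_sd = 0.3,
                       motif_embed_rate = 0.8, background_rate = 0.05,
                       n_decoy_motifs = 4, n_decoy_tfs = 200,
                       tf_effect = 2, tf_noise_sd = 0.22, target_rank = 3,
                       probe_spacing = 5000, probes_per_chrom = 1000,
                       motif_len = 10, window = 100, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- as.list(environment())
  stopifnot(cfg$subtype_fraction > 0, cfg$subtype_fraction <= 1,
            cfg$n_driver_probes <= cfg$n_probes,
            cfg$delta_planted >= 0, cfg$probe_spacing > 2 * cfg$window)
  class(cfg) <- "sim_config"
  cfg
}

rbeta_mean <- function(n, mu, conc) {
  mu <- pmin(pmax(mu, 0.02), 0.98)
  stats::rbeta(n, shape1 = mu * conc, shape2 = (1 - mu) * conc)
}

random_consensus <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

consensus_pwm <- function(motif_id, consensus, p_major = 0.97) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(consensus, "")[[1]]
  probs <- matrix((1 - p_major) / 3, nrow = length(chars), ncol = 4,
                  dimnames = list(NULL, bases))
  probs[cbind(seq_along(chars), match(chars, bases))] <- p_major
  list(motif_id = motif_id, probs = probs, nsites = 100)
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Generate a complete synthetic cohort
#'
#' Produces a probe manifest, enhancer-state BED intervals, a random genome
#' with embedded motif instances, beta and expression matrices, a sample
#' sheet, gene models, PWMs, a TF list, a motif-family map and a truth
#' table. Fully reproducible from `cfg$seed`.
#'
#' Structure: probes sit `probe_spacing` bp apart on synthetic chromosomes;
#' gene TSSs are placed between probes (always > 2 kb from every probe so
#' all probes are distal); a fraction of probes is covered by enhancer-state
#' intervals, and driver probes are drawn from those. Driver probes are
#' hypomethylated in subtype tumors by `delta_planted`; each driver's
#' planted target gene (candidate rank `target_rank`) gains expression
#' `link_effect * (1 - beta)`; the driver TF's expression decreases with the
#' mean driver-probe methylation.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_cohort` with elements `probes`, `enhancers`,
#'   `genome` (DNAStringSet), `beta`, `expr`, `sheet`, `genes`, `pwms`,
#'   `tf_ids`, `family_map`, `truth`, `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  bases <- c("A", "C", "G", "T")

  # ---- layout: probes, chromosomes, genes -----------------------------------
  n_chrom <- ceiling(cfg$n_probes / cfg$probes_per_chrom)
  chrom_of <- rep(seq_len(n_chrom), each = cfg$probes_per_chrom)[
    seq_len(cfg$n_probes)]
  local_i <- sequence(tabulate(chrom_of))
  probes <- data.frame(
    id = sprintf("cg%06d", seq_len(cfg$n_probes)),
    chrom = sprintf("chrS%d", chrom_of),
    pos = as.integer(local_i * cfg$probe_spacing),
    masked = FALSE, stringsAsFactors = FALSE)
  chrom_len <- vapply(seq_len(n_chrom), function(c)
    (sum(chrom_of == c) + 1L) * cfg$probe_spacing, numeric(1))

  genes <- do.call(rbind, lapply(seq_len(n_chrom), function(c) {
    n_g <- sum(chrom_of == c) + 1L  # one TSS in each inter-probe interval
    k <- seq_len(n_g) - 1L
    tss <- as.integer(k * cfg$probe_spacing + cfg$probe_spacing / 2 +
                        sample(-400:400, n_g, replace = TRUE))
    data.frame(gene_id = sprintf("gene_c%d_%04d", c, k),
               chrom = sprintf("chrS%d", c),
               strand = sample(c("+", "-"), n_g, replace = TRUE),
               tss = tss, stringsAsFactors = FALSE)
  }))

  # ---- enhancer states and driver probes ------------------------------------
  n_enh <- floor(cfg$enhancer_fraction * cfg$n_probes)
  enh_idx <- sort(sample(cfg$n_probes, n_enh))
  # drivers are kept far enough apart that no driver's 10-per-side candidate
  # window can reach another driver's planted target gene: otherwise the
  # shared-subtype beta shift makes neighbouring targets genuinely
  # anti-correlated with both probes and the truth table ambiguous
  min_sep <- 10 + cfg$target_rank + 1
  perm <- sample(enh_idx)
  drv_idx <- integer(0)
  for (i in perm) {
    if (length(drv_idx) >= cfg$n_driver_probes) break
    if (!length(drv_idx) || min(abs(i - drv_idx)) >= min_sep) {
      drv_idx <- c(drv_idx, i)
    }
  }
  if (length(drv_idx) < cfg$n_driver_probes)
    stop("config error: cannot place that many separated driver probes",
         call. = FALSE)
  drv_idx <- sort(drv_idx)
  driver_ids <- probes$id[drv_idx]

  states <- c("EnhA1", "EnhA2", "EnhG1", "EnhG2")
  enhancers <- data.frame(
    chrom = probes$chrom[enh_idx],
    start = probes$pos[enh_idx] - 51L,      # 0-based half-open, CpG inside
    end = probes$pos[enh_idx] + 50L,
    label = sample(states, n_enh, replace = TRUE),
    stringsAsFactors = FALSE)
  # decoy non-enhancer states away from probes (exercise label filtering)
  decoy_states <- data.frame(
    chrom = sprintf("chrS%d", sample(n_chrom, 20, replace = TRUE)),
    start = sample(1000L:2000L, 20, replace = TRUE),
    end = 0L, label = sample(c("Quies", "TssA", "ReprPC"), 20,
                             replace = TRUE), stringsAsFactors = FALSE)
  decoy_states$end <- decoy_states$start + 200L
  enhancers <- rbind(enhancers, decoy_states)
  enhancers <- enhancers[order(enhancers$chrom, enhancers$start), ]
  rownames(enhancers) <- NULL

  # masked probes (never drivers)
  mask_pool <- setdiff(seq_len(cfg$n_probes), drv_idx)
  probes$masked[sample(mask_pool, min(cfg$n_masked, length(mask_pool)))] <- TRUE

  # ---- samples ---------------------------------------------------------------
  tumor_ids <- sprintf("tumor_%03d", seq_len(cfg$n_tumor))
  normal_ids <- sprintf("normal_%03d", seq_len(cfg$n_normal))
  subtype <- sort(sample(cfg$n_tumor, round(cfg$subtype_fraction * cfg$n_tumor)))
  sheet <- data.frame(
    sample_id = c(tumor_ids, normal_ids),
    group = c(rep("tumor", cfg$n_tumor), rep("normal", cfg$n_normal)),
    cohort = "SYN",
    subtype = c(ifelse(seq_len(cfg$n_tumor) %in% subtype, "planted", "other"),
                rep(NA_character_, cfg$n_normal)),
    stringsAsFactors = FALSE)
  samples <- sheet$sample_id
  n_s <- length(samples)

  # ---- beta matrix -----------------------------------------------------------
  base_mu <- stats::runif(cfg$n_probes, 0.10, 0.90)
  base_mu[drv_idx] <- stats::runif(length(drv_idx), 0.75, 0.90)
  mu <- matrix(base_mu, nrow = cfg$n_probes, ncol = n_s)
  sub_cols <- which(samples %in% tumor_ids[subtype])
  mu[drv_idx, sub_cols] <- mu[drv_idx, sub_cols] - cfg$delta_planted
  beta <- matrix(rbeta_mean(length(mu), mu, cfg$beta_conc),
                 nrow = cfg$n_probes, ncol = n_s,
                 dimnames = list(probes$id, samples))

  # ---- planted probe-gene links ----------------------------------------------
  links <- do.call(rbind, lapply(drv_idx, function(i) {
    cand <- adjacent_genes(probes[i, ], genes, n_per_side = 10)
    data.frame(probe_id = probes$id[i],
               gene_id = cand$gene_id[cand$rank == cfg$target_rank],
               rank = cfg$target_rank, stringsAsFactors = FALSE)
  }))
  stopifnot(!anyDuplicated(links$gene_id))

  # ---- expression matrix -----------------------------------------------------
  tf_decoys <- sprintf("TF_%03d", seq_len(cfg$n_decoy_tfs))
  driver_tf <- "TF_driver"
  gene_ids <- c(genes$gene_id, tf_decoys, driver_tf)
  b0 <- stats::runif(length(gene_ids), 2, 10)
  expr <- matrix(b0 + stats::rnorm(length(gene_ids) * n_s, sd = cfg$noise_sd),
                 nrow = length(gene_ids), ncol = n_s,
                 dimnames = list(gene_ids, samples))
  for (j in seq_len(nrow(links))) {
    pb <- beta[links$probe_id[j], ]
    expr[links$gene_id[j], ] <- b0[match(links$gene_id[j], gene_ids)] +
      cfg$link_effect * (1 - pb) +
      stats::rnorm(n_s, sd = cfg$noise_sd)
  }
  drv_mean_beta <- colMeans(beta[drv_idx, , drop = FALSE])
  expr[driver_tf, ] <- 8 - cfg$tf_effect * drv_mean_beta +
    stats::rnorm(n_s, sd = cfg$tf_noise_sd)
  expr[expr < 0] <- 0

  # ---- motifs and genome -----------------------------------------------------
  planted_id <- "MOTIF_planted"
  pwms <- list(consensus_pwm(planted_id, random_consensus(cfg$motif_len)))
  for (k in seq_len(cfg$n_decoy_motifs))
    pwms[[k + 1]] <- consensus_pwm(sprintf("MOTIF_dec%02d", k),
                                   random_consensus(cfg$motif_len))
  names(pwms) <- vapply(pwms, `[[`, character(1), "motif_id")
  consensus <- pwms[[planted_id]]$probs
  consensus <- paste(c("A", "C", "G", "T")[apply(consensus, 1, which.max)],
                     collapse = "")

  chroms <- lapply(chrom_len, function(L)
    sample(bases, L, replace = TRUE))
  names(chroms) <- sprintf("chrS%d", seq_len(n_chrom))
  embed <- function(idx_set, rate) {
    emb <- idx_set[stats::runif(length(idx_set)) < rate]
    for (i in emb) {
      ch <- chrom_of[i]
      off <- sample.int(2 * cfg$window - cfg$motif_len + 1, 1) - 1L
      start <- probes$pos[i] - cfg$window + off
      ins <- if (stats::runif(1) < 0.5) consensus else revcomp_chr(consensus)
      chroms[[ch]][start:(start + cfg$motif_len - 1L)] <<-
        strsplit(ins, "")[[1]]
    }
    probes$id[emb]
  }
  embedded_driver <- embed(drv_idx, cfg$motif_embed_rate)
  embedded_bg <- embed(setdiff(enh_idx, drv_idx), cfg$background_rate)
  genome <- Biostrings::DNAStringSet(
    vapply(chroms, paste, character(1), collapse = ""))

  family_map <- list()
  family_map[[planted_id]] <- c(driver_tf, sort(sample(tf_decoys, 3)))

  truth <- list(
    driver_probes = driver_ids,
    links = links,
    subtype_samples = tumor_ids[subtype],
    motif_id = planted_id,
    motif_consensus = consensus,
    embedded_driver_probes = embedded_driver,
    embedded_background_probes = embedded_bg,
    driver_tf = driver_tf,
    masked_probes = probes$id[probes$masked])

  structure(list(probes = probes, enhancers = enhancers, genome = genome,
                 beta = beta, expr = expr, sheet = sheet, genes = genes,
                 pwms = pwms, tf_ids = c(tf_decoys, driver_tf),
                 family_map = family_map, truth = truth, config = cfg),
            class = "sim_cohort")
}

#' Generate a null cohort (no planted effects)
#'
#' Same generator with the beta shift, expression link, TF effect zeroed and
#' the motif embedded everywhere at the background rate only.
#'
#' @param cfg a [sim_config()].
#' @return `sim_cohort`; `truth$null` is TRUE.
#' @export
generate_null_cohort <- function(cfg) {
  cfg$delta_planted <- 0
  cfg$link_effect <- 0
  cfg$tf_effect <- 0
  cfg$motif_embed_rate <- cfg$background_rate
  out <- generate_cohort(cfg)
  out$truth$null <- TRUE
  out
}

#' Write a synthetic cohort to standard-format files
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    manifest = file.path(dir, "probes.tsv"),
    enhancers = file.path(dir, "enhancers.bed"),
    genome = file.path(dir, "genome.fa"),
    beta = file.path(dir, "beta.tsv"),
    expr = file.path(dir, "expression.tsv"),
    sheet = file.path(dir, "samples.tsv"),
    genes = file.path(dir, "genes.tsv"),
    motifs = file.path(dir, "motifs.meme"),
    tf_list = file.path(dir, "tf_list.tsv"),
    family = file.path(dir, "family_map.tsv"),
    truth_probes = file.path(dir, "truth_driver_probes.tsv"),
    truth_links = file.path(dir, "truth_links.tsv"))
  write_probe_manifest(cohort$probes, paths["manifest"])
  write_state_bed(cohort$enhancers, paths["enhancers"])
  Biostrings::writeXStringSet(cohort$genome, paths["genome"])
  write_matrix(cohort$beta, paths["beta"], id_col = "probe_id")
  write_matrix(cohort$expr, paths["expr"], id_col = "gene_id")
  write_sample_sheet(cohort$sheet, paths["sheet"])
  write_gene_models(cohort$genes, paths["genes"])
  write_meme_motifs(cohort$pwms, paths["motifs"])
  utils::write.table(data.frame(gene_id = cohort$tf_ids), paths["tf_list"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fam <- do.call(rbind, lapply(names(cohort$family_map), function(m)
    data.frame(motif_id = m, gene_id = cohort$family_map[[m]],
               stringsAsFactors = FALSE)))
  utils::write.table(fam, paths["family"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(probe_id = cohort$truth$driver_probes),
                     paths["truth_probes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$truth$links, paths["truth_links"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
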