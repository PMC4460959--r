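# Probe universe construction: distal filter against TSSs and enhancer-state
# overlap. Interval arithmetic is delegated to IRanges; coordinate conversion
# between the 1-based CpG position and BED half-open intervals happens only
# here.

#' Merge genomic intervals into a non-overlapping union
#'
#' Produces the per-chromosome sorted, maximal non-overlapping union.
#' Intervals that touch (one ends where the next starts, half-open
#' coordinates) are merged.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `label`.
#' @return data.frame with `chrom`, `start`, `end`, `label` (`"merged"`),
#'   sorted by chromosome then start.
#' @export
merge_regions <- function(intervals) {
  if (!nrow(intervals))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character(),
                      stringsAsFactors = FALSE))
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end))
  red <- GenomicRanges::reduce(gr)  # merges touching ranges by default
  red <- GenomicRanges::sort(red)
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red) - 1L,
             end = GenomicRanges::end(red),
             label = "merged", stringsAsFactors = FALSE)
}

#' Select distal probes (far from every annotated TSS)
#'
#' A probe is retained iff its minimum absolute distance to any TSS exceeds
#' `min_dist` (unstranded bp). Probes on chromosomes without any annotated
#' TSS are retained.
#'
#' @param probes probe manifest data.frame (`id`, `chrom`, `pos`).
#' @param genes gene models data.frame (`gene_id`, `chrom`, `tss`).
#' @param min_dist minimum TSS distance in bp (default 2000).
#' @return character vector of retained probe ids.
#' @export
select_distal <- function(probes, genes, min_dist = 2000) {
  stopifnot(min_dist > 0)
  if (!nrow(genes)) {
    warning("empty gene list: all probes retained as distal")
    return(probes$id)
  }
  keep <- vapply(seq_len(nrow(probes)), function(i) {
    tss <- genes$tss[genes$chrom == probes$chrom[i]]
    if (!length(tss)) return(TRUE)
    min(abs(probes$pos[i] - tss)) > min_dist
  }, logical(1))
  probes$id[keep]
}

#' Select probes falling inside enhancer regions
#'
#' A probe is included iff its 1-based CpG coordinate, converted to 0-based,
#' lies within the half-open span of some interval.
#'
#' @param distal_ids probe ids eligible for selection (the distal set).
#' @param probes probe manifest data.frame.
#' @param enhancers merged interval data.frame (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @return character vector of enhancer probe ids (subset of `distal_ids`).
#' @export
select_enhancer <- function(distal_ids, probes, enhancers) {
  p <- probes[probes$id %in% distal_ids, , drop = FALSE]
  if (!nrow(p) || !nrow(enhancers)) return(character())
  pg <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$pos, width = 1L))
  eg <- GenomicRanges::GRanges(
    enhancers$chrom,
    IRanges::IRanges(start = enhancers$start + 1L, end = enhancers$end))
  hit <- GenomicRanges::countOverlaps(pg, eg) > 0
  p$id[hit]
}

#' Build the probe universe (distal / distal-enhancer partition)
#'
#' Masked probes are dropped first; the remaining probes are partitioned into
#' distal-enhancer probes and distal non-enhancer probes. The non-enhancer
#' distal set is the null pool for the permutation stage of pair linking.
#'
#' @param probes probe manifest data.frame.
#' @param genes gene models data.frame.
#' @param enhancers interval data.frame (merged or not; merged internally).
#' @param min_dist minimum TSS distance (bp).
#' @return object of class `probe_universe`: list with `probes` (unmasked
#'   manifest), `distal`, `distal_enhancer`, `distal_nonenhancer` id vectors.
#' @export
build_probe_universe <- function(probes, genes, enhancers, min_dist = 2000) {
  probes <- probes[!probes$masked, , drop = FALSE]
  merged <- merge_regions(enhancers)
  distal <- select_distal(probes, genes, min_dist = min_dist)
  enh <- select_enhancer(distal, probes, merged)
  out <- list(probes = probes,
              distal = sort(distal),
              distal_enhancer = sort(enh),
              distal_nonenhancer = sort(setdiff(distal, enh)))
  class(out) <- "probe_universe"
  out
}

#' @export
print.probe_universe <- function(x, ...) {
  cat("Probe universe:\n")
  cat(sprintf("  probes (unmasked):      %d\n", nrow(x$probes)))
  cat(sprintf("  distal:                 %d\n", length(x$distal)))
  cat(sprintf("  distal enhancer:        %d\n", length(x$distal_enhancer)))
  cat(sprintf("  distal non-enhancer:    %d\n", length(x$distal_nonenhancer)))
  invisible(x)
}

#' Write a probe universe as a two-column TSV (probe_id, class)
#' @param universe a `probe_universe`.
#' @param path output path.
#' @export
write_probe_universe <- function(universe, path) {
  cls <- ifelse(universe$probes$id %in% universe$distal_enhancer,
                "distal_enhancer",
                ifelse(universe$probes$id %in% universe$distal,
                       "distal_nonenhancer", "proximal"))
  utils::write.table(
    data.frame(probe_id = universe$probes$id, class = cls),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
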