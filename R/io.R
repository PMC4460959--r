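# ---- internal helpers --------------------------------------------------------

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Read a tab/comma separated table with a header
#'
#' Delimiter is sniffed from the first line (tab wins over comma).
#' @noRd
read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#", na.strings = c("NA", ""))
}

# ---- probe manifest ----------------------------------------------------------

#' Read an HM450-style probe manifest
#'
#' The manifest is a TSV/CSV with header columns `id`, `chrom` and `pos`
#' (1-based CpG coordinate). An optional logical/0-1 column `masked` marks
#' probes excluded upstream (assay failure, SNP overlap, repeats); extra
#' columns are ignored.
#'
#' @param path path to the manifest file.
#' @return a `data.frame` with columns `id`, `chrom`, `pos` (integer) and
#'   `masked` (logical).
#' @export
read_probe_manifest <- function(path) {
  df <- read_delim_auto(path)
  need <- c("id", "chrom", "pos")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format("probe manifest %s: missing required column(s) %s",
                path, paste(miss, collapse = ", "))
  pos_num <- suppressWarnings(as.numeric(df$pos))
  bad <- which(is.na(pos_num) | pos_num != floor(pos_num))
  if (length(bad))
    stop_format("probe manifest %s: non-integer pos at data row %d (id=%s)",
                path, bad[1], df$id[bad[1]])
  if (any(pos_num < 1))
    stop_format("probe manifest %s: pos must be >= 1", path)
  if (anyDuplicated(df$id))
    stop_format("probe manifest %s: duplicate probe id %s",
                path, df$id[duplicated(df$id)][1])
  masked <- if ("masked" %in% names(df)) {
    as.logical(df$masked) %in% TRUE
  } else rep(FALSE, nrow(df))
  data.frame(id = as.character(df$id), chrom = as.character(df$chrom),
             pos = as.integer(pos_num), masked = masked,
             stringsAsFactors = FALSE)
}

#' Write a probe manifest
#' @param probes data.frame as returned by [read_probe_manifest()].
#' @param path output path.
#' @export
write_probe_manifest <- function(probes, path) {
  utils::write.table(probes[, c("id", "chrom", "pos", "masked")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- genomic intervals (BED) -------------------------------------------------

#' Read a BED4+ file of annotation states
#'
#' Coordinates are BED-convention 0-based half-open and are preserved as such.
#' Column 4 is the state label (for example a chromHMM state such as `EnhA1`).
#'
#' @param path BED file (>= 4 columns, no header).
#' @param keep_labels optional character vector; if given, only intervals whose
#'   label is in this set are returned.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `label`.
#' @export
read_state_bed <- function(path, keep_labels = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 4)
    stop_format("BED file %s: expected >= 4 columns, found %d", path, ncol(df))
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    label = as.character(df[[4]]),
                    stringsAsFactors = FALSE)
  if (any(out$start < 0))
    stop_format("BED file %s: negative start coordinate", path)
  bad <- which(out$start >= out$end)
  if (length(bad))
    stop_format("BED file %s: start >= end at line %d", path, bad[1])
  if (!is.null(keep_labels))
    out <- out[out$label %in% keep_labels, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write intervals as BED4
#' @param intervals data.frame with chrom, start, end, label.
#' @param path output path.
#' @export
write_state_bed <- function(intervals, path) {
  utils::write.table(intervals[, c("chrom", "start", "end", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# ---- matrices ----------------------------------------------------------------

#' Read a probes-by-samples or genes-by-samples matrix
#'
#' First column holds row ids, header holds sample ids. Empty cells and `NA`
#' tokens become missing values. In `"beta"` mode every non-missing value must
#' lie in \[0, 1\]; in `"expression"` mode values must be non-negative.
#'
#' @param path TSV or CSV file.
#' @param mode `"beta"` or `"expression"`.
#' @return numeric matrix with row ids as rownames, sample ids as colnames.
#' @export
read_matrix <- function(path, mode = c("beta", "expression")) {
  mode <- match.arg(mode)
  df <- read_delim_auto(path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop_format("matrix %s: duplicate row id %s", path,
                ids[duplicated(ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop_format("matrix %s: duplicate sample id", path)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (mode == "beta") {
    bad <- which(!is.na(m) & (m < 0 | m > 1))
    if (length(bad))
      stop_format("beta matrix %s: value %g outside [0,1]", path, m[bad[1]])
  } else {
    bad <- which(!is.na(m) & m < 0)
    if (length(bad))
      stop_format("expression matrix %s: negative value %g", path, m[bad[1]])
  }
  m
}

#' Write a matrix with row ids and a header
#' @param m numeric matrix with rownames and colnames.
#' @param path output path.
#' @param id_col name used for the row-id header column.
#' @export
write_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- sample sheet ------------------------------------------------------------

#' Read a sample sheet
#'
#' Columns: `sample_id`, `group` (tumor/normal), optional `cohort`, optional
#' `subtype`.
#' @param path TSV/CSV file.
#' @return data.frame with those columns (missing optionals filled with NA).
#' @export
read_sample_sheet <- function(path) {
  df <- read_delim_auto(path)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format("sample sheet %s: missing column(s) %s", path,
                paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_format("sample sheet %s: duplicate sample id", path)
  if (!all(df$group %in% c("tumor", "normal")))
    stop_format("sample sheet %s: group must be 'tumor' or 'normal'", path)
  data.frame(sample_id = as.character(df$sample_id),
             group = as.character(df$group),
             cohort = if ("cohort" %in% names(df)) as.character(df$cohort) else NA_character_,
             subtype = if ("subtype" %in% names(df)) as.character(df$subtype) else NA_character_,
             stringsAsFactors = FALSE)
}

#' Write a sample sheet
#' @param sheet data.frame as from [read_sample_sheet()].
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- gene models -------------------------------------------------------------

#' Read gene models (TSS annotation)
#'
#' Accepts either a 4-column TSV with header `gene_id`, `chrom`, `strand`,
#' `tss` (1-based transcription start coordinate, already strand-resolved), or
#' a GTF file (gene features; requires the rtracklayer package).
#'
#' @param path TSV or GTF file.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `tss`.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop_format("reading GTF requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "gene"]
    tss <- ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                  GenomicRanges::end(gr), GenomicRanges::start(gr))
    return(data.frame(gene_id = as.character(gr$gene_id),
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      strand = as.character(GenomicRanges::strand(gr)),
                      tss = as.integer(tss), stringsAsFactors = FALSE))
  }
  df <- read_delim_auto(path)
  need <- c("gene_id", "chrom", "strand", "tss")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format("gene model %s: missing column(s) %s", path,
                paste(miss, collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop_format("gene model %s: strand must be '+' or '-'", path)
  if (any(df$tss < 1))
    stop_format("gene model %s: tss must be >= 1", path)
  data.frame(gene_id = as.character(df$gene_id),
             chrom = as.character(df$chrom),
             strand = as.character(df$strand),
             tss = as.integer(df$tss), stringsAsFactors = FALSE)
}

#' Write gene models as 4-column TSV
#' @param genes data.frame as from [read_gene_models()].
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "chrom", "strand", "tss")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- chromatin loops ---------------------------------------------------------

#' Read a loop set (paired anchor intervals)
#'
#' Six-column TSV (no header): chromA, startA, endA, chromB, startB, endB;
#' anchors are 0-based half-open.
#' @param path input file.
#' @return data.frame with those six columns.
#' @export
read_loops <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 6)
    stop_format("loop file %s: expected 6 columns", path)
  names(df)[1:6] <- c("chromA", "startA", "endA", "chromB", "startB", "endB")
  df[, 1:6]
}

# ---- MEME motifs -------------------------------------------------------------

#' Read PWMs from a MEME-format motif file
#'
#' Supports the MEME minimal motif format with an ACGT alphabet. Each
#' letter-probability row must sum to 1 within `tol` (rows deviating by no
#' more than `tol` are renormalized; larger deviations are format errors).
#'
#' @param path MEME motif file.
#' @param tol per-row tolerance on the probability sum (default 1e-3).
#' @return named list of PWMs; each is a list with `motif_id`, `probs`
#'   (L x 4 matrix, columns A, C, G, T) and `nsites` (NA if absent).
#' @export
read_meme_motifs <- function(path, tol = 1e-3) {
  lines <- readLines(path)
  alpha_line <- grep("^ALPHABET", lines, value = TRUE)
  if (length(alpha_line) && !grepl("ACGT", alpha_line[1]))
    stop_format("MEME file %s: unsupported alphabet (%s)", path, alpha_line[1])
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts))
    stop_format("MEME file %s: no MOTIF blocks found", path)
  out <- list()
  for (s in starts) {
    fields <- strsplit(trimws(lines[s]), "\\s+")[[1]]
    motif_id <- fields[2]
    # find letter-probability header
    h <- s
    while (h <= length(lines) && !grepl("^letter-probability", lines[h])) h <- h + 1
    if (h > length(lines))
      stop_format("MEME file %s: motif %s has no letter-probability matrix",
                  path, motif_id)
    hdr <- lines[h]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr))
      as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", hdr)) else NA_real_
    rows <- matrix(NA_real_, nrow = w, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
    i <- h + 1
    for (r in seq_len(w)) {
      while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1
      vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (length(vals) != 4 || anyNA(vals))
        stop_format("MEME file %s: motif %s row %d is not 4 numbers",
                    path, motif_id, r)
      if (any(vals < 0))
        stop_format("MEME file %s: motif %s row %d has negative probability",
                    path, motif_id, r)
      if (abs(sum(vals) - 1) > tol)
        stop_format("MEME file %s: motif %s row %d sums to %.6f (> %g from 1)",
                    path, motif_id, r, sum(vals), tol)
      rows[r, ] <- vals / sum(vals)
      i <- i + 1
    }
    out[[motif_id]] <- list(motif_id = motif_id, probs = rows, nsites = nsites)
  }
  out
}

#' Write PWMs in MEME minimal motif format
#' @param pwms list of PWMs as from [read_meme_motifs()].
#' @param path output path.
#' @export
write_meme_motifs <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$motif_id), con)
    ns <- if (is.na(p$nsites)) "" else sprintf(" nsites= %g", p$nsites)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d%s",
                       nrow(p$probs), ns), con)
    writeLines(apply(p$probs, 1, function(r)
      paste(sprintf("%.9f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

# ---- cohort matching ---------------------------------------------------------

#' Match samples across methylation, expression and the sample sheet
#'
#' The matched sample list is the intersection of the three sources in
#' lexicographic order; both matrices are column-subset to it and the sheet is
#' row-subset in the same order.
#'
#' @param beta probes x samples beta matrix.
#' @param expr genes x samples expression matrix.
#' @param sheet sample sheet data.frame.
#' @return list with `samples`, `beta`, `expr`, `sheet`.
#' @export
match_cohort <- function(beta, expr, sheet) {
  shared <- sort(intersect(intersect(colnames(beta), colnames(expr)),
                           sheet$sample_id))
  if (!length(shared))
    stop_format("no samples shared between beta, expression and sample sheet")
  list(samples = shared,
       beta = beta[, shared, drop = FALSE],
       expr = expr[, shared, drop = FALSE],
       sheet = sheet[match(shared, sheet$sample_id), , drop = FALSE])
}
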