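#' Read a SEG-like table of copy-number segments
#'
#' Expects a tab-separated file with header columns `sample`, `chrom` (or
#' `chromosome`), `start`, `end`, `copy_number`; coordinates 0-based
#' half-open. Integer copy-number states are derived by half-up rounding of
#' the (possibly fractional) caller copy number. Overlapping segments within
#' one sample/chromosome are rejected.
#'
#' @param path path to the segment table.
#' @param genome a `genome_model`; segment coordinates are validated against
#'   chromosome bounds and names normalized (a "chr" prefix is tolerated).
#' @return data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `copy_number`, `state`, sorted by sample, chromosome, start.
#' @export
read_segments <- function(path, genome) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  names(df)[names(df) == "chromosome"] <- "chrom"
  need <- c("sample", "chrom", "start", "end", "copy_number")
  if (!all(need %in% names(df)))
    stop("segment table must have columns: ", paste(need, collapse = ", "))
  as_segments(df[, need], genome)
}

#' Validate an in-memory segment table
#'
#' @param df data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `copy_number` (and optionally `state`).
#' @inheritParams read_segments
#' @return the validated, sorted segment data.frame with `state` populated.
#' @export
as_segments <- function(df, genome) {
  df$chrom <- normalize_chrom(df$chrom, genome, "segment table")
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$copy_number <- as.numeric(df$copy_number)
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("segments must satisfy 0 <= start < end")
  if (any(df$copy_number < 0)) stop("negative copy number")
  if (any(df$end > chrom_length(genome, df$chrom)))
    stop("segment end beyond chromosome length")
  df$state <- round_half_up(df$copy_number)
  df <- df[order(df$sample, match(df$chrom, genome$chroms$chrom), df$start), ,
           drop = FALSE]
  rownames(df) <- NULL
  by_sc <- split(seq_len(nrow(df)), list(df$sample, df$chrom), drop = TRUE)
  for (idx in by_sc) {
    if (length(idx) > 1 && any(df$start[idx][-1] < df$end[idx][-length(idx)]))
      stop("overlapping segments for sample ", df$sample[idx[1]],
           " on ", df$chrom[idx[1]])
  }
  df
}

# Half-up rounding: 2.4 -> 2, 2.5 -> 3 (base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

#' Read structural variants from a BEDPE file
#'
#' Standard headerless 10-column BEDPE (chrom1 start1 end1 chrom2 start2 end2
#' name score strand1 strand2); an optional 11th column holds the breakpoint
#' homology length (HOMLEN, bp; "." or missing column means unknown) and an
#' optional 12th column the sample id. Breakend positions are the `start`
#' coordinates (0-based). Strands map to breakend orientations
#' (`+` = tail, `-` = head) and the orientation pair gives the join class.
#'
#' @param path path to the BEDPE file.
#' @param genome a `genome_model`.
#' @param sample_id sample id applied to every record when the file has no
#'   sample column.
#' @return data.frame with columns `sv_id`, `sample`, `chrom1`, `pos1`,
#'   `orient1`, `chrom2`, `pos2`, `orient2`, `join_class`, `sv_type`,
#'   `homlen` (NA when unknown).
#' @export
read_svs <- function(path, genome, sample_id = NULL) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 10) stop("BEDPE file must have at least 10 columns")
  homlen <- if (ncol(raw) >= 11) suppressWarnings(as.numeric(raw[[11]])) else NA_real_
  sample <- if (ncol(raw) >= 12) as.character(raw[[12]])
            else if (!is.null(sample_id)) sample_id else "sample"
  df <- data.frame(
    sv_id = as.character(raw[[7]]), sample = sample,
    chrom1 = normalize_chrom(raw[[1]], genome, "BEDPE"),
    pos1 = as.numeric(raw[[2]]), orient1 = strand_to_orient(raw[[9]]),
    chrom2 = normalize_chrom(raw[[4]], genome, "BEDPE"),
    pos2 = as.numeric(raw[[5]]), orient2 = strand_to_orient(raw[[10]]),
    homlen = homlen, stringsAsFactors = FALSE)
  as_svs(df, genome)
}

#' Validate an in-memory structural-variant table
#'
#' @param df data.frame with columns `sv_id`, `sample`, `chrom1`, `pos1`,
#'   `orient1`, `chrom2`, `pos2`, `orient2`, `homlen` (orientations in
#'   \{"head","tail"\}).
#' @inheritParams read_segments
#' @return the validated table with derived `join_class` and `sv_type`.
#' @export
as_svs <- function(df, genome) {
  need <- c("sv_id", "sample", "chrom1", "pos1", "orient1",
            "chrom2", "pos2", "orient2")
  if (!all(need %in% names(df)))
    stop("SV table must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$homlen)) df$homlen <- NA_real_
  df$chrom1 <- normalize_chrom(df$chrom1, genome, "SV table")
  df$chrom2 <- normalize_chrom(df$chrom2, genome, "SV table")
  if (!all(df$orient1 %in% c("head", "tail")) ||
      !all(df$orient2 %in% c("head", "tail")))
    stop("breakend orientations must be 'head' or 'tail'")
  if (any(df$pos1 < 0) || any(df$pos1 >= chrom_length(genome, df$chrom1)) ||
      any(df$pos2 < 0) || any(df$pos2 >= chrom_length(genome, df$chrom2)))
    stop("breakend position outside chromosome bounds")
  if (any(!is.na(df$homlen) & df$homlen < 0))
    stop("negative homology length")
  df$join_class <- paste(df$orient1, df$orient2, sep = "-")
  df$sv_type <- ifelse(df$chrom1 != df$chrom2, "translocation",
                ifelse(df$join_class == "tail-head", "deletion-like",
                ifelse(df$join_class == "head-tail", "duplication-like",
                       "inversion")))
  rownames(df) <- NULL
  df[, c("sv_id", "sample", "chrom1", "pos1", "orient1", "chrom2", "pos2",
         "orient2", "join_class", "sv_type", "homlen")]
}

strand_to_orient <- function(s) {
  s <- as.character(s)
  if (!all(s %in% c("+", "-")))
    stop("malformed strand in BEDPE: ",
         paste(utils::head(unique(setdiff(s, c("+", "-")))), collapse = ", "))
  ifelse(s == "+", "tail", "head")
}

#' @rdname read_svs
#' @param svs a validated SV table.
#' @export
write_svs <- function(svs, path) {
  out <- data.frame(
    svs$chrom1, fmt_bp(svs$pos1), fmt_bp(svs$pos1 + 1),
    svs$chrom2, fmt_bp(svs$pos2), fmt_bp(svs$pos2 + 1),
    svs$sv_id, ".",
    ifelse(svs$orient1 == "tail", "+", "-"),
    ifelse(svs$orient2 == "tail", "+", "-"),
    ifelse(is.na(svs$homlen), ".", fmt_bp(svs$homlen)),
    svs$sample, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(svs)
}

fmt_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read fusion calls
#'
#' Tab-separated with header columns `sample`, `gene_a`, `gene_b`, `chrom_a`,
#' `pos_a`, `chrom_b`, `pos_b`, `confidence` (low/medium/high).
#'
#' @inheritParams read_segments
#' @return validated fusion data.frame with a `fusion_id` column.
#' @export
read_fusions <- function(path, genome) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  as_fusions(df, genome)
}

#' @rdname read_fusions
#' @param df in-memory fusion table.
#' @export
as_fusions <- function(df, genome) {
  need <- c("sample", "gene_a", "gene_b", "chrom_a", "pos_a", "chrom_b",
            "pos_b", "confidence")
  if (!all(need %in% names(df)))
    stop("fusion table must have columns: ", paste(need, collapse = ", "))
  df$chrom_a <- normalize_chrom(df$chrom_a, genome, "fusion table")
  df$chrom_b <- normalize_chrom(df$chrom_b, genome, "fusion table")
  df$pos_a <- as.numeric(df$pos_a)
  df$pos_b <- as.numeric(df$pos_b)
  if (any(df$pos_a < 0) || any(df$pos_a >= chrom_length(genome, df$chrom_a)) ||
      any(df$pos_b < 0) || any(df$pos_b >= chrom_length(genome, df$chrom_b)))
    stop("fusion breakpoint outside chromosome bounds")
  if (!all(df$confidence %in% c("low", "medium", "high")))
    stop("fusion confidence must be low/medium/high")
  if (is.null(df$fusion_id))
    df$fusion_id <- paste0("fus", seq_len(nrow(df)))
  rownames(df) <- NULL
  df[, c("fusion_id", need)]
}

#' Write and read chromothripsis call tables
#'
#' One row per (sample, chromothriptic region) with all call fields; the
#' write/read pair round-trips losslessly.
#'
#' @param calls a call table as produced by [score_cohort()].
#' @param path output (or input) TSV path.
#' @export
write_calls <- function(calls, path) {
  out <- calls
  for (col in c("start", "end", "n_switches", "n_states"))
    out[[col]] <- fmt_bp(out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(calls)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  num <- c("start", "end", "n_switches", "n_states")
  for (col in intersect(num, names(df))) df[[col]] <- as.numeric(df[[col]])
  for (col in intersect(c("canonical", "telomere", "centromere"), names(df)))
    df[[col]] <- as.logical(df[[col]])
  df
}

#' Read a sample metadata table
#'
#' Tab-separated with header; must contain a `sample` column. Typical
#' columns: `entity`, `arm` (WGS/WES), `patient`, `timepoint`, `tert_status`
#' (gain/promoter-mutation/none), `atrx_daxx_trunc` (logical),
#' `germline_gene`, `second_hit` (logical), `tumour_cell_content`, plus one
#' numeric column per signature exposure.
#'
#' @param path input TSV path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!"sample" %in% names(df)) stop("metadata must have a 'sample' column")
  df
}
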