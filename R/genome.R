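#' Genome model: chromosome names, lengths and centromere intervals
#'
#' A `genome_model` holds the ordered chromosome names and lengths of a
#' reference genome plus (optionally) one centromere interval per chromosome.
#' All coordinates in the package are 0-based half-open.
#'
#' @param chroms data.frame with columns `chrom` (character) and `length`
#'   (positive integer-valued), in the desired chromosome order, or a named
#'   numeric vector of lengths.
#' @param centromeres optional data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open, within the chromosome).
#' @return An object of class `genome_model`: a list with elements `chroms`
#'   and `centromeres`.
#' @examples
#' gm <- genome_model(c(chr1 = 1e6, chr2 = 2e6))
#' chrom_length(gm, "chr1")
#' @export
genome_model <- function(chroms, centromeres = NULL) {
  if (is.numeric(chroms) && !is.null(names(chroms))) {
    chroms <- data.frame(chrom = names(chroms), length = unname(chroms),
                         stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(chroms), all(c("chrom", "length") %in% names(chroms)))
  chroms$chrom <- as.character(chroms$chrom)
  chroms$length <- as.numeric(chroms$length)
  if (anyDuplicated(chroms$chrom))
    stop("duplicated chromosome names in genome model")
  if (any(!is.finite(chroms$length)) || any(chroms$length <= 0) ||
      any(chroms$length != round(chroms$length)))
    stop("chromosome lengths must be positive integers")
  if (is.null(centromeres)) {
    centromeres <- data.frame(chrom = character(), start = numeric(),
                              end = numeric(), stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(centromeres),
              all(c("chrom", "start", "end") %in% names(centromeres)))
    centromeres$chrom <- as.character(centromeres$chrom)
    bad <- setdiff(centromeres$chrom, chroms$chrom)
    if (length(bad))
      stop("centromere interval on unknown chromosome: ",
           paste(bad, collapse = ", "))
    if (anyDuplicated(centromeres$chrom))
      stop("more than one centromere interval for a chromosome")
    len <- chroms$length[match(centromeres$chrom, chroms$chrom)]
    if (any(centromeres$start < 0) || any(centromeres$end > len) ||
        any(centromeres$start >= centromeres$end))
      stop("centromere interval outside [0, chromosome length)")
  }
  structure(list(chroms = chroms[, c("chrom", "length")],
                 centromeres = centromeres[, c("chrom", "start", "end")]),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chroms), "chromosomes,",
      nrow(x$centromeres), "centromere intervals\n")
  cat("  total length:", format(sum(x$chroms$length), big.mark = ","), "bp\n")
  invisible(x)
}

#' @rdname genome_model
#' @param genome a `genome_model`.
#' @param chrom chromosome name(s).
#' @export
chrom_length <- function(genome, chrom) {
  stopifnot(inherits(genome, "genome_model"))
  i <- match(chrom, genome$chroms$chrom)
  if (anyNA(i))
    stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  genome$chroms$length[i]
}

# Map chromosome names onto the genome's canonical names, tolerating a
# missing/extra "chr" prefix. Errors on anything unmappable.
normalize_chrom <- function(x, genome, context = "input") {
  canon <- genome$chroms$chrom
  out <- as.character(x)
  miss <- !(out %in% canon)
  if (any(miss)) {
    alt <- ifelse(grepl("^chr", out[miss]), sub("^chr", "", out[miss]),
                  paste0("chr", out[miss]))
    ok <- alt %in% canon
    out[miss][ok] <- alt[ok]
    if (any(!ok))
      stop("unknown chromosome in ", context, ": ",
           paste(unique(out[miss][!ok]), collapse = ", "))
  }
  out
}

centromere_interval <- function(genome, chrom) {
  i <- match(chrom, genome$centromeres$chrom)
  if (is.na(i)) return(NULL)
  c(start = genome$centromeres$start[i], end = genome$centromeres$end[i])
}

#' GRCh37-like human genome model
#'
#' Chromosome lengths of the GRCh37 human assembly (chr1-chr22, chrX, chrY)
#' with the UCSC acen-band centromere intervals. This is the default genome
#' used by the synthetic cohort generator.
#'
#' @return A `genome_model` with 24 chromosomes.
#' @export
grch37_genome <- function() {
  lens <- c(
    chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566)
  cen <- data.frame(
    chrom = names(lens),
    start = c(121535434, 92326171, 90504854, 49660117, 46405641, 58830166,
              58054331, 43838887, 47367679, 39254935, 51644205, 34856694,
              16000000, 16000000, 17000000, 35335801, 22263006, 15460898,
              24681782, 26369569, 11288129, 13000000, 58632012, 10104553),
    end   = c(124535434, 95326171, 93504854, 52660117, 49405641, 61830166,
              61054331, 46838887, 50367679, 42254935, 54644205, 37856694,
              19000000, 19000000, 20000000, 38335801, 25263006, 18460898,
              27681782, 29369569, 14288129, 16000000, 61632012, 13104553),
    stringsAsFactors = FALSE)
  genome_model(lens, cen)
}

#' Read a genome model from chrom.sizes and centromere BED files
#'
#' @param sizes_path path to a UCSC-style chrom.sizes file (two tab-separated
#'   columns: chromosome name, length in bp). Chromosome order is preserved.
#' @param centromere_path optional path to a BED file (0-based half-open) with
#'   one centromere interval per chromosome; rows on chromosomes absent from
#'   the sizes file are an error.
#' @return A `genome_model`.
#' @export
read_genome_model <- function(sizes_path, centromere_path = NULL) {
  sz <- utils::read.table(sizes_path, sep = "\t", header = FALSE,
                          colClasses = "character",
                          col.names = c("chrom", "length")[1:2])
  if (ncol(sz) < 2) stop("chrom.sizes file must have two columns")
  len <- suppressWarnings(as.numeric(sz$length))
  if (anyNA(len) || any(len != round(len)))
    stop("non-integer chromosome length in ", sizes_path)
  gm <- genome_model(data.frame(chrom = sz$chrom, length = len,
                                stringsAsFactors = FALSE))
  if (!is.null(centromere_path) && file.size(centromere_path) > 0) {
    bed <- utils::read.table(centromere_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 3) stop("centromere BED must have at least 3 columns")
    cen <- data.frame(chrom = normalize_chrom(bed[[1]], gm, "centromere BED"),
                      start = as.numeric(bed[[2]]),
                      end = as.numeric(bed[[3]]), stringsAsFactors = FALSE)
    gm <- genome_model(gm$chroms, cen)
  }
  gm
}

#' @rdname read_genome_model
#' @param genome a `genome_model` to write.
#' @param sizes_path,centromere_path output paths.
#' @export
write_genome_model <- function(genome, sizes_path, centromere_path = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  utils::write.table(
    data.frame(genome$chroms$chrom, format(genome$chroms$length, scientific = FALSE, trim = TRUE)),
    sizes_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(centromere_path)) {
    cen <- genome$centromeres
    cen$start <- format(cen$start, scientific = FALSE, trim = TRUE)
    cen$end <- format(cen$end, scientific = FALSE, trim = TRUE)
    utils::write.table(cen, centromere_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(genome)
}

# Half-open interval overlap (all package coordinates are 0-based half-open).
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2
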