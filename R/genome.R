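#' Describe a genome assembly
#'
#' A genome descriptor carries the assembly name, chromosome lengths and
#' (optionally) assembly-gap intervals. It anchors coordinate validation for
#' every downstream stage: net parsing, binning and placement all check their
#' coordinates against the descriptor.
#'
#' @param name Assembly label, e.g. \code{"hg19"}.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param assembly_gaps Optional data.frame (chrom, start, end), 0-based
#'   half-open, of assembly gaps. Overlapping gaps are merged.
#' @return An object of class \code{genome_descriptor}.
#' @export
genome_descriptor <- function(name, chrom_sizes, assembly_gaps = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == ""))
    stop("chrom_sizes must be a named vector")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be positive")
  if (is.null(assembly_gaps)) assembly_gaps <- empty_ivl()
  assembly_gaps <- ivl(assembly_gaps$chrom, assembly_gaps$start, assembly_gaps$end)
  unknown <- setdiff(assembly_gaps$chrom, names(chrom_sizes))
  if (length(unknown))
    stop("assembly gaps on unknown chromosome: ", paste(unknown, collapse = ", "))
  over <- assembly_gaps$end > chrom_sizes[assembly_gaps$chrom]
  if (any(over)) stop("assembly gap extends past chromosome end")
  structure(list(name = name,
                 chrom_sizes = chrom_sizes,
                 assembly_gaps = ivl_reduce(assembly_gaps)),
            class = "genome_descriptor")
}

#' @export
print.genome_descriptor <- function(x, ...) {
  cat("Genome", x$name, "-", length(x$chrom_sizes), "chromosome(s),",
      format(sum(x$chrom_sizes), big.mark = ","), "bp,",
      nrow(x$assembly_gaps), "assembly gap(s)\n")
  invisible(x)
}

#' Read a chromosome-size table
#'
#' Two-column TSV (chromosome name, length in bp) as distributed with UCSC
#' assemblies.
#'
#' @param path File path.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$size, df$chrom)
}

#' Write a chromosome-size table
#' @param chrom_sizes Named numeric vector.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(data.frame(names(chrom_sizes), as.numeric(chrom_sizes)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED interval file
#'
#' Reads the first three (plus optional name) columns of a BED file into the
#' package's 0-based half-open data.frame convention.
#'
#' @param path File path.
#' @return data.frame with columns chrom, start, end and, when present, name.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) return(empty_ivl())
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  out <- ivl(df[[1]], df[[2]], df[[3]])
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  out
}

#' Write intervals as BED
#'
#' @param df data.frame with chrom, start, end and optionally name/score
#'   columns (0-based half-open, BED-native).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_bed <- function(df, path) {
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  utils::write.table(df[, keep, drop = FALSE], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
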