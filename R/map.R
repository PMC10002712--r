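#' Recombination maps
#'
#' A recombination map is an ordered set of loci with cumulative genetic
#' positions (in Morgans) on one or more chromosomes. Maps are used to place
#' causal loci, to compute pairwise recombination fractions (Haldane map
#' function within chromosomes, free recombination across chromosomes), and to
#' drive Poisson-crossover meiosis in the forward simulator.
#'
#' @param chrom character or integer vector of chromosome ids, one per locus.
#' @param pos numeric vector of cumulative genetic positions in Morgans,
#'   non-decreasing within each chromosome.
#' @param id optional locus identifiers (default `locus_1 ... locus_L`).
#' @param chrom_length optional named numeric vector giving the genetic length
#'   (Morgans) of each chromosome; defaults to the largest locus position on
#'   the chromosome. Lengths drive the Poisson crossover count in meiosis.
#' @return An object of class `recomb_map`: a data frame with columns
#'   `chrom`, `id`, `pos` (Morgans) and attributes `chrom_length` and
#'   `total_map_length`.
#' @examples
#' m <- recomb_map(chrom = c(1, 1, 2), pos = c(0, 0.5, 0.2))
#' total_map_length(m)
#' @export
recomb_map <- function(chrom, pos, id = NULL, chrom_length = NULL) {
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  if (length(chrom) != length(pos)) stop("`chrom` and `pos` must have equal length")
  if (length(pos) == 0L) stop("map has no loci")
  if (any(!is.finite(pos)) || any(pos < 0)) stop("positions must be finite and >= 0")
  if (is.null(id)) id <- paste0("locus_", seq_along(pos))
  # preserve chromosome order of first appearance
  chrom <- factor(chrom, levels = unique(chrom))
  for (ch in levels(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p)) {
      stop("malformed map: positions decrease within chromosome ", ch)
    }
  }
  lens <- tapply(pos, chrom, max)
  if (!is.null(chrom_length)) {
    if (is.null(names(chrom_length))) names(chrom_length) <- levels(chrom)
    lens[names(chrom_length)] <- pmax(chrom_length, lens[names(chrom_length)])
  }
  out <- data.frame(chrom = as.character(chrom), id = as.character(id), pos = pos,
                    stringsAsFactors = FALSE)
  attr(out, "chrom_length") <- lens
  attr(out, "total_map_length") <- sum(lens)
  class(out) <- c("recomb_map", "data.frame")
  out
}

#' @export
print.recomb_map <- function(x, ...) {
  cat(sprintf("<recomb_map> %d loci on %d chromosome(s), total length %.3f Morgans\n",
              nrow(x), length(attr(x, "chrom_length")), attr(x, "total_map_length")))
  invisible(x)
}

#' @rdname recomb_map
#' @param map a `recomb_map`.
#' @export
total_map_length <- function(map) attr(map, "total_map_length")

#' @rdname recomb_map
#' @export
chrom_lengths <- function(map) attr(map, "chrom_length")

#' Load a genetic map from a 3-column text file
#'
#' Reads a whitespace- or tab-delimited file with columns
#' (chromosome, marker id, cumulative genetic position). Lines starting with
#' `#` are ignored; a non-numeric first row is treated as a header.
#'
#' @param path path to the map file.
#' @param units units of the position column, `"cM"` (default) or `"Morgan"`.
#' @return a [recomb_map] with positions in Morgans.
#' @examples
#' f <- system.file("extdata", "onechrom_1M.map", package = "gwasconfound")
#' load_genetic_map(f)
#' @export
load_genetic_map <- function(path, units = c("cM", "Morgan")) {
  units <- match.arg(units)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty map file: ", path)
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 3L)) stop("malformed map file: expected 3 columns")
  first_pos <- suppressWarnings(as.numeric(fields[[1L]][3L]))
  if (is.na(first_pos)) fields <- fields[-1L]  # header row
  if (length(fields) == 0L) stop("empty map file: ", path)
  chrom <- vapply(fields, `[[`, "", 1L)
  id <- vapply(fields, `[[`, "", 2L)
  pos <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (any(is.na(pos))) stop("malformed map file: non-numeric positions")
  if (units == "cM") pos <- pos / 100
  recomb_map(chrom, pos, id = id)
}

#' Sex-averaged genetic lengths of the 22 human autosomes
#'
#' Approximate sex-averaged autosomal genetic lengths (centimorgans) of the
#' human linkage map, bundled so that no download is required. The total is
#' about 35.8 Morgans.
#'
#' @return named numeric vector of chromosome lengths in centimorgans.
#' @export
human_autosome_lengths_cm <- function() {
  c(chr1 = 277.7, chr2 = 263.0, chr3 = 224.2, chr4 = 214.5, chr5 = 209.3,
    chr6 = 194.1, chr7 = 187.2, chr8 = 169.2, chr9 = 167.2, chr10 = 174.1,
    chr11 = 161.1, chr12 = 176.0, chr13 = 131.9, chr14 = 125.2, chr15 = 132.4,
    chr16 = 133.8, chr17 = 137.3, chr18 = 129.5, chr19 = 111.1, chr20 = 114.8,
    chr21 = 70.1, chr22 = 79.1)
}

#' A skeleton map of the human autosomes
#'
#' Builds a [recomb_map] whose chromosomes are the 22 human autosomes with the
#' bundled sex-averaged genetic lengths and one marker at each chromosome end,
#' suitable as input to [place_loci()].
#'
#' @return a `recomb_map`.
#' @export
human_autosome_map <- function() {
  len <- human_autosome_lengths_cm() / 100
  recomb_map(chrom = rep(names(len), each = 2L),
             pos = as.numeric(rbind(0, len)))
}

#' A single 1-Morgan chromosome map
#'
#' The simple hypothetical genome used for illustration: one chromosome of
#' total genetic length 1 Morgan.
#'
#' @param n_loci if > 0, place this many evenly spaced loci on the chromosome.
#' @return a `recomb_map`.
#' @export
onechrom_map <- function(n_loci = 2L) {
  m <- recomb_map(chrom = c("chr1", "chr1"), pos = c(0, 1))
  if (n_loci > 2L) m <- place_loci(m, n_loci) else m
}

#' Place loci evenly along a map
#'
#' Allocates `n_loci` to chromosomes proportionally to their genetic length
#' (largest-remainder rounding, so counts always sum exactly to `n_loci`), and
#' spaces loci evenly in genetic-map distance within each chromosome.
#'
#' @param map a [recomb_map] (its chromosome lengths define the genome).
#' @param n_loci number of loci to place (>= 2).
#' @param scheme placement scheme; only `"even_map_distance"` is implemented.
#' @return a `recomb_map` with `n_loci` placed loci.
#' @examples
#' place_loci(onechrom_map(), 5)$pos  # 0, 0.25, 0.5, 0.75, 1
#' @export
place_loci <- function(map, n_loci, scheme = "even_map_distance") {
  scheme <- match.arg(scheme, "even_map_distance")
  if (n_loci < 2L) stop("n_loci must be >= 2")
  lens <- chrom_lengths(map)
  quota <- n_loci * lens / sum(lens)
  k <- floor(quota)
  short <- n_loci - sum(k)
  if (short > 0L) {
    take <- order(quota - k, decreasing = TRUE)[seq_len(short)]
    k[take] <- k[take] + 1L
  }
  chrom <- rep(names(lens), k)
  pos <- unlist(lapply(seq_along(lens), function(i) {
    if (k[i] == 0L) return(numeric(0))
    if (k[i] == 1L) return(lens[[i]] / 2)
    seq(0, lens[[i]], length.out = k[i])
  }), use.names = FALSE)
  recomb_map(chrom, pos, chrom_length = lens)
}

#' Pairwise recombination fraction between two mapped loci
#'
#' Loci on different chromosomes recombine freely (c = 1/2). Within a
#' chromosome the map distance d (Morgans) is converted with the Haldane map
#' function c = (1 - exp(-2 d)) / 2, which matches the Poisson-crossover
#' meiosis used by the simulator.
#'
#' @param map a [recomb_map].
#' @param locus_i,locus_j locus indices (1-based row indices into the map).
#' @return recombination fraction in \[0, 0.5\].
#' @examples
#' m <- recomb_map(c(1, 1), c(0, 1))
#' recomb_fraction(m, 1, 2)  # (1 - exp(-2))/2 = 0.432
#' @export
recomb_fraction <- function(map, locus_i, locus_j) {
  L <- nrow(map)
  if (any(c(locus_i, locus_j) < 1L) || any(c(locus_i, locus_j) > L)) {
    stop("locus index out of range")
  }
  ifelse(map$chrom[locus_i] != map$chrom[locus_j], 0.5,
         haldane(abs(map$pos[locus_i] - map$pos[locus_j])))
}

#' @rdname recomb_fraction
#' @param d map distance in Morgans.
#' @export
haldane <- function(d) (1 - exp(-2 * d)) / 2

#' Full pairwise recombination-fraction matrix
#'
#' @param map a [recomb_map].
#' @return an L x L symmetric matrix of recombination fractions, with zeros on
#'   the diagonal.
#' @export
recomb_matrix <- function(map) {
  d <- abs(outer(map$pos, map$pos, "-"))
  cmat <- haldane(d)
  cmat[outer(map$chrom, map$chrom, "!=")] <- 0.5
  cmat
}

#' Harmonic-mean recombination fraction among mapped loci
#'
#' The number of unordered locus pairs divided by the sum of reciprocal
#' pairwise recombination fractions. This quantity governs how fast
#' selection-generated disequilibrium dissipates; for 1,000 loci spaced evenly
#' along the bundled human autosomal map it is about 0.46.
#'
#' @param map a [recomb_map] with at least 2 loci.
#' @return the harmonic mean recombination fraction, in (0, 0.5\].
#' @examples
#' harmonic_mean_recomb(place_loci(human_autosome_map(), 100))
#' @export
harmonic_mean_recomb <- function(map) {
  L <- nrow(map)
  if (L < 2L) stop("need at least 2 loci")
  cmat <- recomb_matrix(map)
  cc <- cmat[upper.tri(cmat)]
  if (any(cc == 0)) stop("coincident loci: harmonic mean undefined (zero recombination fraction)")
  length(cc) / sum(1 / cc)
}
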