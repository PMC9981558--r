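## Tab-separated I/O. File unit is cM throughout; in-memory unit is Morgans.
## Lines starting '#' are comments; '.' decimal separator; UTF-8.

.CM_PER_MORGAN <- 100

.readTsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop("format error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  x
}

.writeTsv <- function(x, path, header = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a sex-specific linkage map from TSV
#'
#' Expects columns \code{chromosome}, \code{marker}, \code{position_bp},
#' \code{male_cM}, \code{female_cM} (tab-separated; '#' comment lines
#' allowed). The column for the requested sex is converted from cM to
#' Morgans; markers are sorted by map position within chromosome and the
#' chromosome map length d is set to the maximum map position. A chromosome
#' whose markers are all at 0 cM has zero map length and is rejected.
#' Markers whose bp order disagrees with their cM order produce a warning,
#' not an error, since empirical maps carry local ordering noise.
#'
#' @param path TSV file path.
#' @param sex \code{"maternal"} (female_cM) or \code{"paternal"} (male_cM).
#' @return a \linkS4class{LinkageMap}.
#' @seealso \code{\link{writeLinkageMap}}
#' @export
readLinkageMap <- function(path, sex = c("maternal", "paternal")) {
  sex <- match.arg(sex)
  x <- .readTsv(path, c("chromosome", "marker", "position_bp",
                        "male_cM", "female_cM"))
  col <- if (sex == "maternal") "female_cM" else "male_cM"
  cm <- suppressWarnings(as.numeric(x[[col]]))
  keep <- !is.na(cm)
  if (any(cm[keep] < 0)) {
    row <- which(!is.na(cm) & cm < 0)[1L]
    stop("validation error: negative cM at row ", row)
  }
  x <- x[keep, , drop = FALSE]
  m <- data.frame(marker = as.character(x$marker),
                  chromosome = as.character(x$chromosome),
                  position_bp = as.integer(x$position_bp),
                  map_pos = cm[keep] / .CM_PER_MORGAN,
                  stringsAsFactors = FALSE)
  m <- m[order(m$chromosome, m$map_pos, m$position_bp), , drop = FALSE]
  rownames(m) <- NULL
  d <- tapply(m$map_pos, m$chromosome, max)
  if (any(d <= 0))
    stop("validation error: chromosome has zero map length: ",
         paste(names(d)[d <= 0], collapse = ", "))
  for (ch in names(d)) {
    sub <- m[m$chromosome == ch, ]
    if (is.unsorted(sub$position_bp, strictly = FALSE))
      warning("chromosome ", ch,
              ": physical (bp) order disagrees with map (cM) order")
  }
  new("LinkageMap", markers = m, sex = sex,
      d = stats::setNames(as.numeric(d), names(d)))
}

#' Write a linkage map to TSV
#'
#' Inverse of \code{\link{readLinkageMap}}: map positions are written in cM
#' into the column matching the map's sex; the other sex column is left
#' empty. Round-trips are lossless to 1e-9 Morgans.
#'
#' @param map a \linkS4class{LinkageMap}.
#' @param path output TSV path.
#' @param header optional comment line (written prefixed with '# ').
#' @export
writeLinkageMap <- function(map, path, header = NULL) {
  stopifnot(is(map, "LinkageMap"))
  m <- map@markers
  cm <- format(m$map_pos * .CM_PER_MORGAN, digits = 15, trim = TRUE,
               scientific = FALSE)
  out <- data.frame(chromosome = m$chromosome, marker = m$marker,
                    position_bp = m$position_bp,
                    male_cM = if (map@sex == "paternal") cm else "",
                    female_cM = if (map@sex == "maternal") cm else "",
                    stringsAsFactors = FALSE)
  .writeTsv(out, path, header)
  invisible(path)
}

#' Read gamete crossover records from TSV
#'
#' Expects columns \code{meiosis_id}, \code{sex}, \code{chromosome},
#' \code{crossovers_cM} — the last a comma-separated list of crossover map
#' positions in cM; an empty string means zero crossovers. Positions are
#' converted to Morgans and sorted ascending per record.
#'
#' @param path TSV file path.
#' @param map optional \linkS4class{LinkageMap}: when given, positions are
#'   validated against the chromosome map lengths.
#' @return a \linkS4class{GameteCrossoverSet}.
#' @export
readGameteCrossovers <- function(path, map = NULL) {
  x <- .readTsv(path, c("meiosis_id", "sex", "chromosome", "crossovers_cM"))
  pos <- lapply(as.character(x$crossovers_cM), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(numeric(0))
    v <- as.numeric(strsplit(s, ",", fixed = TRUE)[[1L]])
    if (anyNA(v)) stop("malformed crossover position list: ", s)
    sort(v) / .CM_PER_MORGAN
  })
  rec <- data.frame(meiosis_id = as.character(x$meiosis_id),
                    sex = as.character(x$sex),
                    chromosome = as.character(x$chromosome),
                    stringsAsFactors = FALSE)
  rec$positions <- pos
  g <- new("GameteCrossoverSet", records = rec)
  if (!is.null(map)) {
    d <- map@d
    for (i in seq_len(nrow(rec))) {
      ch <- rec$chromosome[i]
      if (ch %in% names(d) && length(pos[[i]]) &&
          max(pos[[i]]) > d[[ch]] + 1e-12)
        stop("validation error: crossover position beyond map length on ",
             ch, " (record ", rec$meiosis_id[i], ")")
    }
  }
  g
}

#' Write gamete crossover records to TSV
#'
#' @param g a \linkS4class{GameteCrossoverSet}.
#' @param path output TSV path.
#' @param header optional comment line.
#' @export
writeGameteCrossovers <- function(g, path, header = NULL) {
  stopifnot(is(g, "GameteCrossoverSet"))
  rec <- g@records
  out <- data.frame(meiosis_id = rec$meiosis_id, sex = rec$sex,
                    chromosome = rec$chromosome,
                    crossovers_cM = vapply(rec$positions, function(p)
                      paste(format(p * .CM_PER_MORGAN, digits = 15,
                                   trim = TRUE, scientific = FALSE),
                            collapse = ","), character(1)),
                    stringsAsFactors = FALSE)
  .writeTsv(out, path, header)
  invisible(path)
}

#' Read bivalent crossover-count distributions from TSV
#'
#' Expects columns \code{chromosome}, \code{sex}, \code{n},
#' \code{probability}: one row per (chromosome, sex, count). Counts absent
#' from the file get probability 0.
#'
#' @param path TSV file path.
#' @return a list of \linkS4class{BivalentDistribution}, one per
#'   (chromosome, sex) present.
#' @export
readBivalentDistributions <- function(path) {
  x <- .readTsv(path, c("chromosome", "sex", "n", "probability"))
  sp <- split(x, paste(x$chromosome, x$sex, sep = "\r"))
  lapply(unname(sp), function(s) {
    BivalentDistribution(stats::setNames(as.numeric(s$probability),
                                         as.integer(s$n)),
                         chromosome = as.character(s$chromosome[1L]),
                         sex = as.character(s$sex[1L]))
  })
}

#' Write bivalent distributions to TSV
#'
#' @param dists a \linkS4class{BivalentDistribution} or list of them.
#' @param path output TSV path.
#' @param header optional comment line.
#' @export
writeBivalentDistributions <- function(dists, path, header = NULL) {
  if (is(dists, "BivalentDistribution")) dists <- list(dists)
  out <- do.call(rbind, lapply(dists, function(d)
    data.frame(chromosome = d@chromosome, sex = d@sex,
               n = seq_along(d@probs) - 1L,
               probability = format(d@probs, digits = 15, trim = TRUE,
                                    scientific = FALSE),
               stringsAsFactors = FALSE)))
  .writeTsv(out, path, header)
  invisible(path)
}

#' Histogram of gametic crossover counts
#'
#' Tallies the number of meiotic products with 0..N observed crossovers for
#' one chromosome and sex — the sufficient statistic for EM inference of the
#' bivalent distribution.
#'
#' @param g a \linkS4class{GameteCrossoverSet}.
#' @param chromosome,sex restrict to these records.
#' @return integer vector \code{c_0..c_N} named by count, with N the maximum
#'   observed count; sums to the number of selected records.
#' @export
countsPerRecord <- function(g, chromosome, sex) {
  stopifnot(is(g, "GameteCrossoverSet"))
  rec <- g@records
  sel <- rec$chromosome == chromosome & rec$sex == sex
  if (!any(sel))
    stop("no gamete records for chromosome ", chromosome, ", sex ", sex)
  k <- vapply(rec$positions[sel], length, integer(1))
  N <- max(k)
  stats::setNames(tabulate(k + 1L, nbins = N + 1L), 0:N)
}
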