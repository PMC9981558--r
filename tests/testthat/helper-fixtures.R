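# Fixture builders and independent oracles shared across tests.

# LinkageMap built directly from cM positions (per-chromosome named list).
makeMap <- function(cm, sex = "maternal", d_cM = NULL) {
  rows <- do.call(rbind, lapply(names(cm), function(ch) {
    p <- sort(cm[[ch]])
    data.frame(marker = sprintf("%s_m%02d", ch, seq_along(p)),
               chromosome = ch,
               position_bp = as.integer(seq_along(p) * 1000L),
               map_pos = p / 100, stringsAsFactors = FALSE)
  }))
  d <- if (is.null(d_cM)) vapply(cm, max, numeric(1)) / 100 else d_cM / 100
  new("LinkageMap", markers = rows, sex = sex,
      d = stats::setNames(as.numeric(d), names(cm)))
}

# GameteCrossoverSet from a list of cM position vectors.
makeGametes <- function(positions_cM, chromosome = "chr1", sex = "maternal") {
  rec <- data.frame(meiosis_id = sprintf("g%03d", seq_along(positions_cM)),
                    sex = sex, chromosome = chromosome,
                    stringsAsFactors = FALSE)
  rec$positions <- lapply(positions_cM, function(p) sort(p) / 100)
  new("GameteCrossoverSet", records = rec)
}

# Write a linkage-map TSV from raw cM columns (both sexes).
writeMapTsv <- function(path, chromosome, marker, position_bp,
                        male_cM = "", female_cM = "") {
  df <- data.frame(chromosome = chromosome, marker = marker,
                   position_bp = position_bp, male_cM = male_cM,
                   female_cM = female_cM, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent placement oracle for the no-crossover probability given k:
# brute-force uniform draws in the k equal regions, no package code involved.
mcP0Placement <- function(m_i, m_j, d, k, nDraws) {
  if (k == 0) return(list(p = 1, se = 0))
  w <- d / k
  hit <- logical(nDraws)
  pos <- matrix(rep((seq_len(k) - 1) * w, each = nDraws) +
                  stats::runif(nDraws * k) * w, nrow = nDraws)
  p <- mean(rowSums(pos > m_i & pos <= m_j) == 0)
  list(p = p, se = sqrt(p * (1 - p) / nDraws))
}

# Random bivalent distribution over counts 0..nmax (optionally without 0).
randomDist <- function(nmax = 4, allowZero = TRUE) {
  probs <- stats::runif(nmax + 1)
  if (!allowZero) probs[1] <- 0
  BivalentDistribution(probs / sum(probs))
}
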