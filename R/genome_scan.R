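## Trait-orthogonal genome scans: segregation distortion from per-bin
## founder frequencies, and recombination hotspot / suppression windows
## from population breakpoint density.

#' Per-bin founder counts
#'
#' @param bg a \code{bin_genotypes}.
#' @param K number of founders.
#' @return bins x K matrix of line counts (rows sum to the bin's non-NA
#'   line count).
#' @export
bin_founder_freqs <- function(bg, K = 8) {
  t(apply(bg$G, 2, function(col) tabulate(col[!is.na(col)], K)))
}

#' Chi-square test of equal founder transmission
#'
#' Pearson chi-square of the observed founder counts against equal
#' expected shares n/K, df = K - 1.
#'
#' @param counts length-K count vector, or a bins x K matrix (vectorised).
#' @return list with \code{statistic} and \code{p} (per row for a
#'   matrix).
#' @export
distortion_test <- function(counts) {
  if (is.matrix(counts)) {
    K <- ncol(counts)
    if (K < 2) stop("need at least 2 founder classes")
    n <- rowSums(counts)
    exp_c <- n / K
    stat <- rowSums((counts - exp_c)^2) / exp_c
    stat[n == 0] <- NA
    return(list(statistic = stat, p = pchisq(stat, K - 1,
                                             lower.tail = FALSE)))
  }
  K <- length(counts)
  if (K < 2) stop("need at least 2 founder classes")
  n <- sum(counts)
  if (n == 0) stop("zero total count")
  exp_c <- n / K
  stat <- sum((counts - exp_c)^2 / exp_c)
  list(statistic = stat, p = pchisq(stat, K - 1, lower.tail = FALSE))
}

#' Merge significant bins into segregation-distortion regions
#'
#' Bins significant after Bonferroni correction over all tested bins are
#' merged into regions when adjacent, allowing a gap of at most one
#' non-significant bin.  Regions are ranked by their minimum p.
#'
#' @param p per-bin p-values (from \code{\link{distortion_test}}).
#' @param bin_map the \code{bin_map}.
#' @param counts optional bins x K count matrix used to report the most
#'   over- and under-represented founders at the minimum-p bin.
#' @param alpha family-wise level before Bonferroni division.
#' @return data.frame of regions: chrom, start, end, n_bins, min_p,
#'   over_founder, under_founder.
#' @export
merge_distortion_regions <- function(p, bin_map, counts = NULL,
                                     alpha = 0.05) {
  m <- sum(!is.na(p))
  sig <- !is.na(p) & p < alpha / m
  if (!any(sig))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_bins = integer(0),
                      min_p = numeric(0), over_founder = integer(0),
                      under_founder = integer(0)))
  out <- list()
  for (c in unique(bin_map$chrom)) {
    bi <- which(bin_map$chrom == c)
    s <- sig[bi]
    if (!any(s)) next
    ## merge runs separated by a gap of at most 1 non-significant bin
    idx <- which(s)
    grp <- cumsum(c(1, diff(idx) > 2))
    for (g in unique(grp)) {
      members <- idx[grp == g]
      span <- min(members):max(members)
      pm <- p[bi[members]]
      best <- bi[members[which.min(pm)]]
      over <- under <- NA_integer_
      if (!is.null(counts)) {
        dev <- counts[best, ] - sum(counts[best, ]) / ncol(counts)
        over <- which.max(dev)
        under <- which.min(dev)
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = c, start = bin_map$start[bi[min(span)]],
        end = bin_map$end[bi[max(span)]], n_bins = length(members),
        min_p = min(pm), over_founder = over, under_founder = under)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$min_p), ]
  rownames(res) <- NULL
  res
}

#' Recombination hotspot / suppression windows
#'
#' The genome is tiled with fixed windows; per window the population
#' breakpoint count (label changes between adjacent bins, summed over
#' lines, located at the bin boundary) is compared to the genome-wide
#' mean rate by a two-sided Poisson test with BH correction: upper-tail
#' significant windows are hotspots, lower-tail ones suppression.  A
#' partial last window is rate-normalised by its true length.
#'
#' @param bg a \code{bin_genotypes}.
#' @param chrom_lengths named bp chromosome lengths.
#' @param genetic_map optional output of
#'   \code{\link{genetic_map_from_bins}} for a cM/Mb column.
#' @param window_bp window size (default 1 Mb).
#' @param q_cut BH q-value cutoff for calls.
#' @return data.frame: chrom, start, end, breakpoints, bp_per_mb,
#'   cm_per_mb, p, q, call.
#' @export
recomb_windows <- function(bg, chrom_lengths, genetic_map = NULL,
                           window_bp = 1e6, q_cut = 0.05) {
  if (window_bp <= 0) stop("window_bp must be > 0")
  map <- bg$map
  ## population breakpoint positions (boundary of bin b, weight = lines
  ## changing label there)
  bp_pos <- bp_chrom <- bp_w <- list()
  for (c in unique(map$chrom)) {
    bi <- which(map$chrom == c)
    if (length(bi) < 2) next
    w <- vapply(seq_along(bi)[-1], function(j) {
      a <- bg$G[, bi[j - 1]]; b <- bg$G[, bi[j]]
      sum(!is.na(a) & !is.na(b) & a != b)
    }, 0)
    bp_pos[[c]] <- map$end[bi[-length(bi)]]
    bp_chrom[[c]] <- rep(c, length(w))
    bp_w[[c]] <- w
  }
  out <- list()
  for (c in names(chrom_lengths)) {
    L <- chrom_lengths[[c]]
    starts <- seq(1, L, by = window_bp)
    ends <- pmin(starts + window_bp - 1, L)
    cnt <- numeric(length(starts))
    if (!is.null(bp_pos[[c]])) {
      wi <- findInterval(bp_pos[[c]], starts)
      for (j in seq_along(wi)) cnt[wi[j]] <- cnt[wi[j]] + bp_w[[c]][j]
    }
    cm <- rep(NA_real_, length(starts))
    if (!is.null(genetic_map)) {
      gm <- genetic_map[genetic_map$chrom == c, ]
      mids <- floor((gm$start + gm$end) / 2)
      cm <- vapply(seq_along(starts), function(j)
        sum(gm$cm[mids >= starts[j] & mids <= ends[j]]), 0)
    }
    out[[c]] <- data.frame(chrom = c, start = starts, end = ends,
                           breakpoints = cnt,
                           mb = (ends - starts + 1) / 1e6, cm = cm)
  }
  win <- do.call(rbind, out)
  rate <- sum(win$breakpoints) / sum(win$mb)   # per Mb
  mu <- rate * win$mb
  p_lo <- ppois(win$breakpoints, mu)
  p_hi <- ppois(win$breakpoints - 1, mu, lower.tail = FALSE)
  win$p <- pmin(1, 2 * pmin(p_lo, p_hi))
  win$q <- p.adjust(win$p, "BH")
  win$call <- ifelse(win$q < q_cut & win$breakpoints > mu, "hotspot",
                     ifelse(win$q < q_cut & win$breakpoints < mu,
                            "suppression", "background"))
  win$bp_per_mb <- win$breakpoints / win$mb
  win$cm_per_mb <- win$cm / win$mb
  rownames(win) <- NULL
  win[, c("chrom", "start", "end", "breakpoints", "bp_per_mb",
          "cm_per_mb", "p", "q", "call")]
}
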