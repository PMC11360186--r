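## Population bin map: merge all lines' ancestry segment boundaries into
## bins, label each line at each bin, and derive population summaries and
## a genetic map.

#' Build the population bin map from ancestry segments
#'
#' Bin boundaries are the sorted union of all lines' segment boundaries on
#' each chromosome.  Bins shorter than \code{min_bin_bp} are merged into
#' their shorter neighbour (tie: left), which minimises boundary
#' displacement.
#'
#' @param segments data.frame with columns line, chrom, start, end,
#'   founder (e.g. from \code{\link{infer_ancestry}} or
#'   \code{\link{mosaic_segments}}).
#' @param chrom_lengths named bp lengths of the chromosomes.
#' @param min_bin_bp minimum retained bin length (default 5000).
#' @return a \code{bin_map} data.frame (chrom, start, end, bin) with
#'   attributes \code{min_bin_bp} and \code{n_lines}.
#' @export
build_bins <- function(segments, chrom_lengths, min_bin_bp = 5000) {
  if (nrow(segments) == 0) stop("no segments supplied")
  out <- list()
  for (c in names(chrom_lengths)) {
    L <- chrom_lengths[[c]]
    segc <- segments[segments$chrom == c, ]
    cuts <- sort(unique(segc$end))
    cuts <- cuts[cuts < L]
    ends <- c(cuts, L)
    ## merge bins shorter than min_bin_bp into the shorter neighbour
    repeat {
      starts <- c(1, head(ends, -1) + 1)
      len <- ends - starts + 1
      short <- which(len < min_bin_bp)
      if (length(short) == 0 || length(ends) == 1) break
      i <- short[which.min(len[short])]
      left_len <- if (i > 1) len[i - 1] else Inf
      right_len <- if (i < length(ends)) len[i + 1] else Inf
      if (left_len <= right_len) {
        ends <- ends[-(i - 1)]   # absorb into left neighbour
      } else {
        ends <- ends[-i]         # absorb into right neighbour
      }
    }
    starts <- c(1, head(ends, -1) + 1)
    out[[c]] <- data.frame(chrom = c, start = starts, end = ends)
  }
  bm <- do.call(rbind, out)
  bm$bin <- seq_len(nrow(bm))
  rownames(bm) <- NULL
  structure(bm, class = c("bin_map", "data.frame"),
            min_bin_bp = min_bin_bp,
            n_lines = length(unique(segments$line)))
}

#' Label every line at every bin
#'
#' The bin label is the founder ancestry of the segment covering the bin
#' midpoint (identical to a per-bp majority vote except at merged
#' slivers).  Uncovered midpoints give NA with a warning.
#'
#' @param bin_map a \code{bin_map}.
#' @param segments ancestry segments (one record per line segment; for
#'   diploid truth segments pass one haplotype, or inferred homozygous
#'   segments).
#' @return a \code{bin_genotypes} list: \code{map}, \code{G} (lines x
#'   bins integer founder labels), \code{line_ids}.
#' @export
bin_genotypes <- function(bin_map, segments) {
  lines <- unique(segments$line)
  mids <- floor((bin_map$start + bin_map$end) / 2)
  G <- matrix(NA_integer_, nrow = length(lines), ncol = nrow(bin_map))
  seg_by <- split(segments, segments$line)
  n_uncovered <- 0
  for (i in seq_along(lines)) {
    s <- seg_by[[lines[i]]]
    for (c in unique(bin_map$chrom)) {
      bi <- which(bin_map$chrom == c)
      sc <- s[s$chrom == c, ]
      if (nrow(sc) == 0) { n_uncovered <- n_uncovered + length(bi); next }
      sc <- sc[order(sc$start), ]
      j <- findInterval(mids[bi], sc$start)
      hit <- j >= 1 & mids[bi] <= sc$end[pmax(j, 1)]
      G[i, bi[hit]] <- sc$founder[j[hit]]
      n_uncovered <- n_uncovered + sum(!hit)
    }
  }
  if (n_uncovered > 0)
    warning(n_uncovered, " bin midpoints uncovered; set to NA")
  structure(list(map = bin_map, G = G, line_ids = lines),
            class = "bin_genotypes")
}

#' @method print bin_genotypes
#' @export
print.bin_genotypes <- function(x, ...) {
  cat("bin_genotypes:", nrow(x$G), "lines x", ncol(x$G), "bins\n")
  invisible(x)
}

#' Length-weighted founder genome shares
#'
#' @param bg a \code{bin_genotypes}.
#' @param K number of founders.
#' @return list with \code{per_line} (lines x K matrix; rows sum to 1
#'   over non-NA territory) and \code{population} (column means).
#'   All-NA lines are excluded with a warning.
#' @export
founder_contribution <- function(bg, K = 8) {
  len <- bg$map$end - bg$map$start + 1
  per <- t(apply(bg$G, 1, function(row) {
    ok <- !is.na(row)
    if (!any(ok)) return(rep(NA_real_, K))
    vapply(seq_len(K), function(k) sum(len[ok][row[ok] == k]), 0) /
      sum(len[ok])
  }))
  rownames(per) <- bg$line_ids
  bad <- apply(is.na(per), 1, all)
  if (any(bad)) {
    warning(sum(bad), " all-NA lines excluded from population shares")
  }
  list(per_line = per, population = colMeans(per[!bad, , drop = FALSE]))
}

#' Breakpoint (junction) statistics per line
#'
#' A junction is a label change between consecutive non-NA bins of a line.
#'
#' @param bg a \code{bin_genotypes}.
#' @return list with \code{per_line} junction counts, \code{total}, and
#'   \code{bins_per_line} (junctions + number of chromosomes covered).
#' @export
breakpoint_stats <- function(bg) {
  chrom <- bg$map$chrom
  per <- apply(bg$G, 1, function(row) {
    sum(vapply(unique(chrom), function(c) {
      r <- row[chrom == c]
      r <- r[!is.na(r)]
      if (length(r) < 2) 0L else sum(diff(r) != 0L)
    }, 0L))
  })
  names(per) <- bg$line_ids
  covered <- apply(bg$G, 1, function(row)
    length(unique(chrom[!is.na(row)])))
  list(per_line = per, total = sum(per), bins_per_line = per + covered)
}

#' Genetic map from adjacent-bin breakpoint frequencies
#'
#' The observed frequency of label changes between adjacent bins
#' (\code{r_obs}) is converted to a meiotic recombination fraction by
#' \code{r_meiotic = r_obs / expansion_factor} (capped at 0.49, with a
#' warning), then to map distance by Haldane's function
#' d = -50 ln(1 - 2 r) cM.  The population accumulates recombination over
#' the funnel and selfing generations, so \code{expansion_factor} absorbs
#' the design's map expansion; the default 1 reports the expanded
#' (population-scale) map.
#'
#' @param bg a \code{bin_genotypes}.
#' @param expansion_factor positive scale factor.
#' @return data.frame (chrom, bin, start, end, r_obs, cm, cum_cm) with
#'   attribute \code{total_cm}.
#' @export
genetic_map_from_bins <- function(bg, expansion_factor = 1) {
  if (expansion_factor <= 0) stop("expansion_factor must be > 0")
  map <- bg$map
  r_obs <- numeric(nrow(map))  # r between bin i-1 and i (0 for chrom start)
  for (c in unique(map$chrom)) {
    bi <- which(map$chrom == c)
    for (j in seq_along(bi)[-1]) {
      a <- bg$G[, bi[j - 1]]; b <- bg$G[, bi[j]]
      ok <- !is.na(a) & !is.na(b)
      r_obs[bi[j]] <- if (any(ok)) mean(a[ok] != b[ok]) else 0
    }
  }
  r_mei <- r_obs / expansion_factor
  capped <- r_mei > 0.49
  if (any(capped)) {
    warning(sum(capped), " intervals capped at r = 0.49")
    r_mei[capped] <- 0.49
  }
  cm <- -50 * log(1 - 2 * r_mei)
  cum <- numeric(length(cm))
  for (c in unique(map$chrom)) {
    bi <- which(map$chrom == c)
    cum[bi] <- cumsum(cm[bi])
  }
  out <- data.frame(chrom = map$chrom, bin = map$bin, start = map$start,
                    end = map$end, r_obs = r_obs, cm = cm, cum_cm = cum)
  attr(out, "total_cm") <- sum(cm)
  out
}

#' Haldane map function
#'
#' d = -50 ln(1 - 2 r) centimorgans.
#' @param r recombination fraction in [0, 0.5).
#' @export
haldane_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must be in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' Raw-genotype population summaries
#'
#' @param geno a \code{geno_matrix}.
#' @return list with \code{het_fraction} (het calls / non-NA calls),
#'   \code{missing_rate}, and \code{snp_per_kb} per chromosome (requires
#'   chromosome lengths via \code{chrom_lengths}).
#' @param chrom_lengths optional named bp lengths for SNP density.
#' @export
population_summaries <- function(geno, chrom_lengths = NULL) {
  g <- geno$G
  n_call <- sum(!is.na(g))
  het <- if (n_call == 0) 0 else sum(g == 1L, na.rm = TRUE) / n_call
  miss <- mean(is.na(g))
  dens <- NULL
  if (!is.null(chrom_lengths)) {
    dens <- vapply(names(chrom_lengths), function(c)
      sum(geno$marker_chrom == c) / (chrom_lengths[[c]] / 1000), 0)
  }
  list(het_fraction = het, missing_rate = miss, snp_per_kb = dens)
}

#' Principal-component variance diagnostics
#'
#' PCA of the centred dosage (or founder-label indicator) matrix; returns
#' the proportion of total variance carried by each component.
#'
#' @param G numeric lines x markers matrix (NA imputed to column means).
#' @return list with \code{var_shares} (sums to 1) and \code{scores}
#'   (first 10 PCs).
#' @export
structure_diagnostics <- function(G) {
  G <- as.matrix(G)
  for (j in seq_len(ncol(G))) {
    na <- is.na(G[, j])
    if (any(na)) G[na, j] <- mean(G[, j], na.rm = TRUE)
  }
  sds <- apply(G, 2, sd)
  G <- G[, sds > 0, drop = FALSE]
  if (ncol(G) == 0) stop("constant matrix: variance shares undefined")
  pc <- prcomp(G, center = TRUE, scale. = FALSE)
  shares <- pc$sdev^2 / sum(pc$sdev^2)
  list(var_shares = shares,
       scores = pc$x[, seq_len(min(10, ncol(pc$x))), drop = FALSE])
}

#' Linkage-disequilibrium decay curve
#'
#' Mean r^2 between marker dosages in distance windows; the decay
#' distance is the start of the first window whose mean r^2 falls below
#' \code{r2_threshold}.
#'
#' @param geno a \code{geno_matrix}.
#' @param max_dist maximum pair distance in bp.
#' @param window_bp distance-window width.
#' @param max_pairs subsampling cap on marker pairs per chromosome.
#' @param r2_threshold decay threshold (default 0.2).
#' @param seed RNG seed for pair subsampling.
#' @return list with \code{curve} (data.frame dist_mid, mean_r2, n) and
#'   \code{decay_distance} (bp, NA if never below threshold).
#' @export
ld_decay <- function(geno, max_dist = 2e6, window_bp = 1e5,
                     max_pairs = 20000, r2_threshold = 0.2, seed = 1) {
  set.seed(seed)
  d_all <- r2_all <- list()
  for (c in unique(geno$marker_chrom)) {
    sel <- which(geno$marker_chrom == c)
    if (length(sel) < 2) next
    pos <- geno$marker_pos[sel]
    i <- sample(sel, min(length(sel), 2000))
    prs <- expand.grid(a = i, b = i)
    prs <- prs[prs$a < prs$b, ]
    d <- abs(geno$marker_pos[prs$a] - geno$marker_pos[prs$b])
    keep <- d > 0 & d <= max_dist
    prs <- prs[keep, ]; d <- d[keep]
    if (nrow(prs) > max_pairs) {
      pick <- sample.int(nrow(prs), max_pairs)
      prs <- prs[pick, ]; d <- d[pick]
    }
    r2 <- vapply(seq_len(nrow(prs)), function(j) {
      x <- geno$G[, prs$a[j]]; y <- geno$G[, prs$b[j]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
      cor(x[ok], y[ok])^2
    }, 0)
    d_all[[c]] <- d; r2_all[[c]] <- r2
  }
  d <- unlist(d_all); r2 <- unlist(r2_all)
  ok <- !is.na(r2)
  d <- d[ok]; r2 <- r2[ok]
  win <- floor((d - 1) / window_bp)
  curve <- data.frame(
    dist_mid = (sort(unique(win)) + 0.5) * window_bp,
    mean_r2 = as.numeric(tapply(r2, win, mean)),
    n = as.integer(table(win)))
  below <- which(curve$mean_r2 < r2_threshold)
  list(curve = curve,
       decay_distance = if (length(below)) curve$dist_mid[min(below)] -
         window_bp / 2 else NA_real_)
}
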