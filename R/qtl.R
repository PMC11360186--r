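## Dual QTL discovery: SNP-level GWAS (OLS dosage regression, BH
## threshold, locus clumping) and bin-level multiallelic linkage scanning
## (stepwise cofactor selection, interval exclusion, permutation LOD
## threshold), plus PVE, founder effects, and offset-distance resolution.

#' SNP-level genome-wide association scan
#'
#' Ordinary least squares of the phenotype on each SNP's allele dosage,
#' with optional covariates (e.g. leading principal components).  The
#' population is expected to have weak structure, so the default uses no
#' covariates.  Two-sided p-values come from the slope t statistic; the
#' genomic-inflation factor (median chi-square / 0.4549) is attached.
#'
#' @param geno a \code{geno_matrix}.
#' @param phenotype numeric vector of line phenotypes (order of
#'   \code{geno$line_ids}).
#' @param covariates optional numeric matrix of per-line covariates.
#' @param min_genotype_count SNPs whose minor genotype class has fewer
#'   lines are skipped (flagged, p = NA).
#' @return a \code{gwas_result} data.frame (chrom, pos, effect, se, t, p,
#'   skipped) with attribute \code{lambda_gc}.
#' @export
gwas_lm <- function(geno, phenotype, covariates = NULL,
                    min_genotype_count = 5) {
  y <- as.numeric(phenotype)
  n <- length(y)
  if (n != nrow(geno$G)) stop("phenotype length must match lines")
  if (n < 30) stop("need at least 30 lines")
  C <- cbind(rep(1, n), covariates)
  ## residualize y on covariates once; per-SNP NA handled by subsetting
  M <- ncol(geno$G)
  eff <- se <- tt <- pp <- rep(NA_real_, M)
  skipped <- logical(M)
  q_c <- qr(C)
  y_r <- qr.resid(q_c, y)
  no_na <- !anyNA(geno$G)
  for (j in seq_len(M)) {
    x <- geno$G[, j]
    ok <- !is.na(x)
    tab <- tabulate(x[ok] + 1L, 3L)
    if (sum(tab > 0) < 2 || sum(tab[tab > 0][-which.max(tab[tab > 0])]) <
        min_genotype_count) {
      skipped[j] <- TRUE
      next
    }
    if (all(ok)) {
      x_r <- qr.resid(q_c, x)
      yr <- y_r
      df <- n - ncol(C) - 1
    } else {
      qc <- qr(C[ok, , drop = FALSE])
      x_r <- qr.resid(qc, x[ok])
      yr <- qr.resid(qc, y[ok])
      df <- sum(ok) - ncol(C) - 1
    }
    sxx <- sum(x_r^2)
    if (sxx < 1e-12 || df < 1) {
      skipped[j] <- TRUE
      next
    }
    b <- sum(x_r * yr) / sxx
    rss <- sum(yr^2) - b^2 * sxx
    s2 <- max(rss, 0) / df
    eff[j] <- b
    se[j] <- sqrt(s2 / sxx)
    tt[j] <- if (se[j] == 0) sign(b) * .Machine$double.xmax else b / se[j]
    pp[j] <- max(2 * pt(-abs(tt[j]), df), .Machine$double.xmin)
  }
  res <- data.frame(chrom = geno$marker_chrom, pos = geno$marker_pos,
                    effect = eff, se = se, t = tt, p = pp,
                    skipped = skipped)
  chi <- tt[!is.na(tt)]^2
  attr(res, "lambda_gc") <- if (length(chi)) median(chi) / 0.4549364 else NA
  class(res) <- c("gwas_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up threshold
#'
#' Standard step-up rule at FDR level \code{fdr}: the cutoff is the
#' largest sorted p-value p(i) with p(i) <= i * fdr / m; the discovery
#' set is every p at or below the cutoff.  An empty discovery set gives
#' cutoff 0.
#'
#' @param p p-values in (0, 1].
#' @param fdr false-discovery-rate level.
#' @return list with \code{cutoff} and \code{discoveries} (indices into
#'   \code{p}).
#' @export
bh_threshold <- function(p, fdr = 0.05) {
  p_use <- p[!is.na(p)]
  m <- length(p_use)
  if (m == 0) return(list(cutoff = 0, discoveries = integer(0)))
  s <- sort(p_use)
  ok <- which(s <= seq_len(m) * fdr / m)
  cutoff <- if (length(ok)) s[max(ok)] else 0
  list(cutoff = cutoff, discoveries = which(!is.na(p) & p <= cutoff))
}

#' Clump significant SNPs into loci
#'
#' Greedy positional merge: consecutive significant SNPs on a chromosome
#' closer than \code{window_bp} join one locus (equivalent to transitive
#' closure under the distance relation); the lead SNP is the smallest p.
#'
#' @param gwas a \code{gwas_result}.
#' @param cutoff p-value threshold defining significance.
#' @param window_bp merge window (default 600 kb, about the short end of
#'   the population's LD-decay range).
#' @return data.frame of loci: chrom, start, end, lead_pos, lead_p,
#'   n_snps.
#' @export
clump_loci <- function(gwas, cutoff, window_bp = 6e5) {
  sig <- gwas[!is.na(gwas$p) & gwas$p <= cutoff, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), lead_pos = numeric(0),
                      lead_p = numeric(0), n_snps = integer(0)))
  out <- list()
  for (c in unique(sig$chrom)) {
    sc <- sig[sig$chrom == c, ]
    sc <- sc[order(sc$pos), ]
    grp <- cumsum(c(1, diff(sc$pos) > window_bp))
    for (g in unique(grp)) {
      sg <- sc[grp == g, ]
      lead <- which.min(sg$p)
      out[[length(out) + 1]] <- data.frame(
        chrom = c, start = min(sg$pos), end = max(sg$pos),
        lead_pos = sg$pos[lead], lead_p = sg$p[lead],
        n_snps = nrow(sg))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## one-way RSS of y on a founder-label factor; returns c(rss, groups used)
.factor_rss <- function(y, lab) {
  ok <- !is.na(lab) & !is.na(y)
  y <- y[ok]; lab <- lab[ok]
  if (length(y) == 0) return(c(NA, 0, 0))
  gs <- tapply(y, lab, sum)
  gn <- tapply(y, lab, length)
  rss <- sum(y^2) - sum(gs^2 / gn)
  c(rss, length(gn), length(y))
}

#' Stepwise cofactor selection over bins (ICIM-style)
#'
#' Forward-backward stepwise selection of bin founder-factors on the
#' phenotype: at each forward step the eligible bin with the smallest
#' added-term F-test p-value enters if p < \code{p_in}; backward steps
#' drop any selected bin whose deletion p-value exceeds \code{p_out}.
#' Deterministic given the data.
#'
#' @param bg a \code{bin_genotypes}.
#' @param phenotype per-line phenotype vector.
#' @param p_in,p_out entry and removal thresholds.
#' @param min_group_n bins are eligible only if at least two founder
#'   groups have this many lines.
#' @param max_cofactors hard cap on the model size.
#' @return integer vector of selected bin indices (possibly empty).
#' @export
icim_cofactors <- function(bg, phenotype, p_in = 0.001, p_out = 0.002,
                           min_group_n = 10, max_cofactors = 20) {
  y <- as.numeric(phenotype)
  eligible <- which(apply(bg$G, 2, function(lab) {
    tab <- table(lab[!is.na(lab)])
    sum(tab >= min_group_n) >= 2
  }))
  selected <- integer(0)
  complete_ok <- function(bins) {
    ok <- !is.na(y)
    for (b in bins) ok <- ok & !is.na(bg$G[, b])
    ok
  }
  rss_rank <- function(bins, ok) {
    if (length(bins) == 0) {
      X <- matrix(1, sum(ok), 1)
    } else {
      f <- as.data.frame(lapply(bins, function(b) factor(bg$G[ok, b])))
      names(f) <- paste0("b", bins)
      X <- model.matrix(~ ., data = f)
    }
    q <- qr(X)
    c(sum(qr.resid(q, y[ok])^2), q$rank)
  }
  ## F-test p-value for the terms in `full` beyond those in `base`,
  ## on lines complete for the full set
  step_p <- function(base, full) {
    ok <- complete_ok(full)
    if (sum(ok) < 4) return(NA_real_)
    f0 <- rss_rank(base, ok)
    f1 <- rss_rank(full, ok)
    df1 <- f1[2] - f0[2]
    df2 <- sum(ok) - f1[2]
    if (df1 < 1 || df2 < 1 || f1[1] <= 0) return(NA_real_)
    F <- ((f0[1] - f1[1]) / df1) / (f1[1] / df2)
    pf(F, df1, df2, lower.tail = FALSE)
  }
  repeat {
    changed <- FALSE
    ## forward step
    if (length(selected) < max_cofactors) {
      cand <- setdiff(eligible, selected)
      if (length(cand)) {
        ps <- vapply(cand, function(b)
          step_p(selected, c(selected, b)), 0)
        if (any(!is.na(ps)) && min(ps, na.rm = TRUE) < p_in) {
          selected <- c(selected, cand[which.min(ps)])
          changed <- TRUE
        }
      }
    }
    ## backward steps
    while (length(selected) > 1) {
      ps <- vapply(seq_along(selected), function(i)
        step_p(selected[-i], selected), 0)
      if (any(!is.na(ps)) && max(ps, na.rm = TRUE) > p_out) {
        selected <- selected[-which.max(ps)]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  sort(selected)
}

#' Bin-level multiallelic linkage scan
#'
#' For each bin the phenotype is adjusted for the cofactor bins lying
#' outside \code{exclusion_window_bp} of the tested bin (residuals + grand
#' mean), then LOD = (n/2) log10(RSS0/RSS1) contrasts the bin's founder
#' factor against the intercept-only null.  Lines with NA at the tested
#' bin are dropped per bin.
#'
#' @param bg a \code{bin_genotypes}.
#' @param phenotype per-line phenotype vector.
#' @param cofactors integer bin indices (e.g. from
#'   \code{\link{icim_cofactors}}).
#' @param exclusion_window_bp cofactors within this distance of the
#'   tested bin (same chromosome, midpoint distance) are excluded from
#'   the adjustment.
#' @param min_group_n founder group means are reported only for groups
#'   with at least this many lines.
#' @return a \code{linkage_scan} data.frame: chrom, start, end, bin, lod,
#'   n, plus founder-mean columns \code{mean_1..mean_K} and counts
#'   \code{n_1..n_K}; attribute \code{cofactors}.
#' @export
linkage_scan <- function(bg, phenotype, cofactors = integer(0),
                         exclusion_window_bp = 1e7, min_group_n = 10) {
  y <- as.numeric(phenotype)
  map <- bg$map
  B <- nrow(map)
  K <- max(bg$G, na.rm = TRUE)
  mids <- floor((map$start + map$end) / 2)
  lod <- rep(NA_real_, B)
  nn <- integer(B)
  gmeans <- matrix(NA_real_, B, K)
  gns <- matrix(0L, B, K)
  adj_cache <- new.env(parent = emptyenv())
  adjust_y <- function(cof_use) {
    key <- paste0("k", paste(cof_use, collapse = ","))
    if (!is.null(adj_cache[[key]])) return(adj_cache[[key]])
    if (length(cof_use) == 0) {
      adj_cache[[key]] <- y
      return(y)
    }
    f <- as.data.frame(lapply(cof_use, function(b) factor(bg$G[, b])))
    names(f) <- paste0("b", cof_use)
    ok <- !Reduce(`|`, lapply(f, is.na)) & !is.na(y)
    X <- model.matrix(~ ., data = f[ok, , drop = FALSE])
    ya <- rep(NA_real_, length(y))
    ya[ok] <- qr.resid(qr(X), y[ok]) + mean(y[ok])
    adj_cache[[key]] <- ya
    ya
  }
  for (b in seq_len(B)) {
    cof_use <- cofactors[!(map$chrom[cofactors] == map$chrom[b] &
                           abs(mids[cofactors] - mids[b]) <=
                             exclusion_window_bp)]
    ya <- adjust_y(cof_use)
    lab <- bg$G[, b]
    ok <- !is.na(lab) & !is.na(ya)
    if (sum(ok) < 3) next
    yy <- ya[ok]; ll <- lab[ok]
    tabn <- tapply(yy, ll, length)
    if (length(tabn) < 2) next
    gs <- tapply(yy, ll, sum)
    rss1 <- sum(yy^2) - sum(gs^2 / tabn)
    rss0 <- sum((yy - mean(yy))^2)
    nn[b] <- length(yy)
    lod[b] <- if (rss0 <= 1e-300) 0 else if (rss1 <= 0) Inf else
      max(0, (length(yy) / 2) * log10(rss0 / rss1))
    km <- as.integer(names(tabn))
    gns[b, km] <- as.integer(tabn)
    means <- tapply(yy, ll, mean)
    keep <- tabn >= min_group_n
    gmeans[b, km[keep]] <- means[keep]
  }
  res <- data.frame(chrom = map$chrom, start = map$start, end = map$end,
                    bin = map$bin, lod = lod, n = nn)
  colnames(gmeans) <- paste0("mean_", seq_len(K))
  colnames(gns) <- paste0("n_", seq_len(K))
  res <- cbind(res, gmeans, gns)
  attr(res, "cofactors") <- cofactors
  class(res) <- c("linkage_scan", "data.frame")
  res
}

#' Permutation threshold for the genome-wide maximum LOD
#'
#' The phenotype is permuted across lines \code{n_perm} times; each
#' permutation's genome-wide maximum LOD from a plain (cofactor-free)
#' interval scan is recorded, and the threshold is the empirical
#' (1 - alpha) quantile.  Cofactor re-selection per permutation can be
#' enabled but defaults off: under the permutation null the cofactor set
#' is empty in expectation, and the plain scan keeps the null
#' distribution deterministic and cheap.
#'
#' @param bg a \code{bin_genotypes}.
#' @param phenotype per-line phenotype vector.
#' @param n_perm number of permutations (>= 100).
#' @param alpha genome-wide type-I level.
#' @param seed RNG seed (permutations are seed-reproducible).
#' @param reselect_cofactors if TRUE, run
#'   \code{\link{icim_cofactors}} + \code{\link{linkage_scan}} per
#'   permutation (slow).
#' @param ... passed to the per-permutation pipeline when
#'   \code{reselect_cofactors} is TRUE.
#' @return list with \code{threshold} and \code{max_lods} (length
#'   \code{n_perm}).
#' @export
permutation_threshold <- function(bg, phenotype, n_perm = 1000,
                                  alpha = 0.05, seed = 1,
                                  reselect_cofactors = FALSE, ...) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  set.seed(seed)
  y <- as.numeric(phenotype)
  n <- length(y)
  P <- vapply(seq_len(n_perm), function(i) sample(y), numeric(n))
  if (reselect_cofactors) {
    max_lods <- vapply(seq_len(n_perm), function(i) {
      cof <- icim_cofactors(bg, P[, i], ...)
      max(linkage_scan(bg, P[, i], cof, ...)$lod, na.rm = TRUE)
    }, 0)
  } else {
    B <- ncol(bg$G)
    max_lods <- rep(-Inf, n_perm)
    sum_sq <- colSums(P^2)
    for (b in seq_len(B)) {
      lab <- bg$G[, b]
      ok <- !is.na(lab)
      if (sum(ok) < 3) next
      ll <- factor(lab[ok])
      if (nlevels(ll) < 2) next
      N <- model.matrix(~ ll - 1)
      gn <- colSums(N)
      Yb <- P[ok, , drop = FALSE]
      gs <- crossprod(N, Yb)                       # groups x n_perm
      rss1 <- colSums(Yb^2) - colSums(gs^2 / gn)
      rss0 <- colSums(Yb^2) - colSums(Yb)^2 / sum(ok)
      lods <- (sum(ok) / 2) * log10(pmax(rss0, 1e-300) /
                                    pmax(rss1, 1e-300))
      max_lods <- pmax(max_lods, pmax(lods, 0))
    }
  }
  list(threshold = as.numeric(quantile(max_lods, 1 - alpha, type = 1)),
       max_lods = max_lods)
}

#' Call QTLs from a linkage scan
#'
#' Contiguous runs of bins at or above the threshold form one QTL
#' (adjacent QTLs are separated by at least one sub-threshold bin).  The
#' lead bin is the maximum LOD; the support interval extends outward from
#' the lead until LOD drops more than 1.5 below the peak.
#'
#' @param scan a \code{linkage_scan}.
#' @param threshold LOD threshold (e.g. from
#'   \code{\link{permutation_threshold}}).
#' @param drop LOD drop defining the support interval (default 1.5).
#' @return data.frame of QTLs: chrom, lead_bin, lead_start, lead_end,
#'   peak_lod, ci_start_bin, ci_end_bin, ci_start, ci_end.
#' @export
call_qtls <- function(scan, threshold, drop = 1.5) {
  out <- list()
  for (c in unique(scan$chrom)) {
    sc <- scan[scan$chrom == c, ]
    above <- !is.na(sc$lod) & sc$lod >= threshold
    if (!any(above)) next
    grp <- cumsum(c(1, diff(above) != 0))
    for (g in unique(grp[above])) {
      idx <- which(grp == g & above)
      peak <- idx[which.max(sc$lod[idx])]
      lim <- sc$lod[peak] - drop
      lo <- peak
      while (lo > 1 && !is.na(sc$lod[lo - 1]) && sc$lod[lo - 1] >= lim)
        lo <- lo - 1
      hi <- peak
      while (hi < nrow(sc) && !is.na(sc$lod[hi + 1]) &&
             sc$lod[hi + 1] >= lim)
        hi <- hi + 1
      out[[length(out) + 1]] <- data.frame(
        chrom = c, lead_bin = sc$bin[peak], lead_start = sc$start[peak],
        lead_end = sc$end[peak], peak_lod = sc$lod[peak],
        ci_start_bin = sc$bin[lo], ci_end_bin = sc$bin[hi],
        ci_start = sc$start[lo], ci_end = sc$end[hi])
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), lead_bin = integer(0),
                      lead_start = numeric(0), lead_end = numeric(0),
                      peak_lod = numeric(0), ci_start_bin = integer(0),
                      ci_end_bin = integer(0), ci_start = numeric(0),
                      ci_end = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' PVE and founder allele effects at a QTL lead bin
#'
#' PVE is 100 x R-squared of the single-bin founder-factor model; founder
#' effects are group means centred on the grand mean; the additive effect
#' range is half the spread between the largest and smallest group means
#' among founders with at least \code{min_group_n} lines.
#'
#' @param bg a \code{bin_genotypes}.
#' @param phenotype per-line phenotype vector.
#' @param lead_bin bin index.
#' @param min_group_n minimum group size entering the effect range.
#' @return list with \code{pve} (percent), \code{effects} (length-K,
#'   NA for absent founders), \code{n} per founder, and
#'   \code{additive_range} (days).
#' @export
pve_and_effects <- function(bg, phenotype, lead_bin, min_group_n = 10) {
  y <- as.numeric(phenotype)
  lab <- bg$G[, lead_bin]
  ok <- !is.na(lab) & !is.na(y)
  yy <- y[ok]; ll <- lab[ok]
  K <- max(bg$G, na.rm = TRUE)
  gn <- tapply(yy, ll, length)
  gm <- tapply(yy, ll, mean)
  rss1 <- sum(yy^2) - sum(tapply(yy, ll, sum)^2 / gn)
  rss0 <- sum((yy - mean(yy))^2)
  pve <- if (rss0 <= 0) 0 else 100 * (1 - rss1 / rss0)
  effects <- nvec <- rep(NA_real_, K)
  km <- as.integer(names(gm))
  effects[km] <- gm - mean(yy)
  nvec[km] <- gn
  big <- gm[gn >= min_group_n]
  rng <- if (length(big) >= 2) (max(big) - min(big)) / 2 else NA_real_
  list(pve = pve, effects = effects, n = nvec, additive_range = rng)
}

#' Offset distance between a known gene and a QTL lead bin
#'
#' 0 if the gene overlaps the lead bin; otherwise the coordinate
#' difference between the facing edges (an abutting gene is 1 bp away).
#' The bin offset counts whole bins strictly between gene and lead bin.
#' Genes on another chromosome give NA.
#'
#' @param qtl one row of \code{\link{call_qtls}} output (or any list with
#'   chrom, lead_start, lead_end).
#' @param gene list or row with chrom, start, end.
#' @param bin_map the \code{bin_map} used for the scan.
#' @return list with \code{bp} and \code{bins}.
#' @export
offset_distance <- function(qtl, gene, bin_map) {
  if (gene$chrom != qtl$chrom) return(list(bp = NA_real_, bins = NA_integer_))
  if (gene$start <= qtl$lead_end && gene$end >= qtl$lead_start)
    return(list(bp = 0, bins = 0L))
  if (gene$end < qtl$lead_start) {
    gap <- c(gene$end, qtl$lead_start)
  } else {
    gap <- c(qtl$lead_end, gene$start)
  }
  between <- bin_map$chrom == qtl$chrom & bin_map$start > gap[1] &
    bin_map$end < gap[2]
  list(bp = gap[2] - gap[1], bins = sum(between))
}
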