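## Founder panel: eight inbred parents, two subspecies-like groups,
## biallelic markers stored per chromosome.

#' Default founder names and subspecies-like group labels
#'
#' Eight inbred rice-like founders: four Xian-like (group "A") and four
#' Geng-like (group "B").
#' @export
magic_founders <- function() {
  list(
    ids = c("ZS97", "MH63", "9311", "XS134", "AUS449", "MITAK", "NIP", "WYJ3"),
    group = c("A", "A", "A", "B", "A", "B", "B", "B")
  )
}

#' Simulate an eight-founder marker panel
#'
#' Draws biallelic SNP alleles for eight inbred founders split into two
#' diverged groups.  Per-marker group allele frequencies follow a
#' Balding-Nichols model: an ancestral frequency p is drawn uniformly, and
#' each group's frequency is drawn from Beta(p(1-F)/F, (1-p)(1-F)/F) with
#' F = \code{divergence}; founder alleles are Bernoulli draws from their
#' group frequency.  \code{divergence = 0} collapses both groups onto the
#' ancestral frequency, so group labels carry no allele-frequency signal.
#' Monomorphic markers are dropped, so every retained marker is polymorphic
#' in at least one founder pair.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length(s) in bp (recycled).
#' @param marker_density expected markers per bp (e.g. 5e-4 = 5 per 10 kb).
#' @param divergence between-group differentiation parameter F in [0, 1).
#' @param founder_ids,group_label founder names and group labels (length 8).
#' @param seed optional RNG seed.
#' @return A \code{founder_panel}: list with \code{founder_ids},
#'   \code{group}, \code{chrom_names}, \code{chrom_lengths} (named bp
#'   vector), and \code{markers}, a per-chromosome list of
#'   \code{list(pos, alleles)} where \code{alleles} is a founders x markers
#'   0/1 matrix.
#' @export
simulate_founders <- function(n_chrom = 3, chrom_length = 30e6,
                              marker_density = 5e-4, divergence = 0.55,
                              founder_ids = magic_founders()$ids,
                              group_label = magic_founders()$group,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_chrom < 1) stop("n_chrom must be >= 1")
  chrom_length <- rep_len(as.numeric(chrom_length), n_chrom)
  if (any(chrom_length <= 0)) stop("chromosome lengths must be positive")
  if (marker_density <= 0) stop("marker_density must be positive")
  if (length(founder_ids) != length(group_label))
    stop("founder_ids and group_label must have equal length")
  if (divergence < 0 || divergence >= 1) stop("divergence must be in [0, 1)")
  K <- length(founder_ids)
  chrom_names <- paste0("chr", seq_len(n_chrom))
  markers <- vector("list", n_chrom)
  names(markers) <- chrom_names
  for (c in seq_len(n_chrom)) {
    L <- chrom_length[c]
    m <- max(2L, round(L * marker_density))
    pos <- sort(sample.int(L, m, replace = FALSE))
    p_anc <- runif(m, 0.15, 0.85)
    if (divergence > 0) {
      a <- p_anc * (1 - divergence) / divergence
      b <- (1 - p_anc) * (1 - divergence) / divergence
      pA <- rbeta(m, a, b)
      pB <- rbeta(m, a, b)
    } else {
      pA <- pB <- p_anc
    }
    alleles <- matrix(0L, nrow = K, ncol = m)
    for (k in seq_len(K)) {
      pk <- if (group_label[k] == group_label[1]) pA else pB
      alleles[k, ] <- rbinom(m, 1L, pk)
    }
    poly <- colSums(alleles) > 0L & colSums(alleles) < K
    markers[[c]] <- list(pos = pos[poly], alleles = alleles[, poly, drop = FALSE])
  }
  structure(list(
    founder_ids = founder_ids,
    group = setNames(group_label, founder_ids),
    chrom_names = chrom_names,
    chrom_lengths = setNames(chrom_length, chrom_names),
    markers = markers
  ), class = "founder_panel")
}

#' @method print founder_panel
#' @export
print.founder_panel <- function(x, ...) {
  cat("founder_panel:", length(x$founder_ids), "founders,",
      length(x$chrom_names), "chromosomes,",
      sum(vapply(x$markers, function(m) length(m$pos), 0)), "markers\n")
  invisible(x)
}

n_markers <- function(panel) {
  sum(vapply(panel$markers, function(m) length(m$pos), 0))
}

#' Hudson's FST between the two founder groups
#'
#' Mean-of-ratios Hudson estimator over all markers, contrasting group "A"
#' and group "B" founders.
#' @param panel a \code{founder_panel}.
#' @return FST estimate (ratio of summed numerators to summed denominators).
#' @export
founder_fst <- function(panel) {
  g <- panel$group
  iA <- which(g == unique(g)[1])
  iB <- which(g != unique(g)[1])
  n1 <- length(iA); n2 <- length(iB)
  num <- den <- 0
  for (c in seq_along(panel$markers)) {
    al <- panel$markers[[c]]$alleles
    p1 <- colMeans(al[iA, , drop = FALSE])
    p2 <- colMeans(al[iB, , drop = FALSE])
    num <- num + sum((p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1))
    den <- den + sum(p1 * (1 - p2) + p2 * (1 - p1))
  }
  num / den
}
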