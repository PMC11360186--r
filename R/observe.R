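## Genotype observation: project mosaics onto the founder marker panel and
## add genotyping error, emulating resequencing-based calls.

#' Observe marker genotypes of simulated lines
#'
#' The true genotype at a marker is the sum of the two haplotypes' founder
#' alleles (0/1/2).  Observation error: a true homozygote is miscalled as
#' the opposite homozygote with probability \code{e_hom} and as a
#' heterozygote with probability \code{e_het}; a true heterozygote is
#' miscalled as either homozygote with probability \code{e_hom} each.
#' Calls are set missing (NA) with probability \code{missing_rate} first.
#'
#' @param mosaics list of \code{mosaic} objects.
#' @param panel a \code{founder_panel}.
#' @param e_hom,e_het,missing_rate error-model rates in [0, 1],
#'   \code{e_hom + e_het <= 1}.
#' @param seed optional RNG seed.
#' @return a \code{geno_matrix}: list with \code{G} (lines x markers
#'   integer matrix in 0/1/2/NA), \code{line_ids}, \code{marker_chrom},
#'   \code{marker_pos}.
#' @export
observe_genotypes <- function(mosaics, panel, e_hom = 0.005, e_het = 0.005,
                              missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(c(e_hom, e_het, missing_rate) < 0) ||
      any(c(e_hom, e_het, missing_rate) > 1) || e_hom + e_het > 1)
    stop("error rates must be in [0, 1] with e_hom + e_het <= 1")
  G <- true_genotypes(mosaics, panel)
  n <- length(G$G)
  if (missing_rate > 0) G$G[runif(n) < missing_rate] <- NA_integer_
  if (e_hom > 0 || e_het > 0) {
    u <- runif(n)
    g <- G$G
    hom <- !is.na(g) & g != 1L
    het <- !is.na(g) & g == 1L
    flip_hom <- hom & u < e_hom
    to_het <- hom & u >= e_hom & u < e_hom + e_het
    g[flip_hom] <- 2L - g[flip_hom]
    g[to_het] <- 1L
    if (e_hom > 0) {
      bad_het <- het & u < e_hom
      g[bad_het] <- ifelse(runif(sum(bad_het)) < 0.5, 0L, 2L)
    }
    G$G <- g
  }
  G
}

#' Error-free genotypes implied by the mosaics
#'
#' @inheritParams observe_genotypes
#' @return a \code{geno_matrix} (see \code{\link{observe_genotypes}}).
#' @export
true_genotypes <- function(mosaics, panel) {
  n <- length(mosaics)
  chroms <- panel$chrom_names
  mc <- unlist(lapply(chroms, function(c)
    rep(c, length(panel$markers[[c]]$pos))))
  mp <- unlist(lapply(chroms, function(c) panel$markers[[c]]$pos))
  G <- matrix(NA_integer_, nrow = n, ncol = length(mp))
  for (i in seq_len(n)) {
    row <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      c <- chroms[ci]
      pos <- panel$markers[[c]]$pos
      al <- panel$markers[[c]]$alleles
      idx <- seq_along(pos)
      f1 <- founder_at(mosaics[[i]]$haps[[1]][[c]], pos)
      f2 <- founder_at(mosaics[[i]]$haps[[2]][[c]], pos)
      row[[ci]] <- al[cbind(f1, idx)] + al[cbind(f2, idx)]
    }
    G[i, ] <- unlist(row)
  }
  line_ids <- vapply(mosaics, function(m)
    if (is.na(m$line_id)) "" else m$line_id, "")
  if (any(line_ids == "")) line_ids <- sprintf("MG%04d", seq_len(n))
  structure(list(G = G, line_ids = line_ids,
                 marker_chrom = mc, marker_pos = mp),
            class = "geno_matrix")
}

#' @method print geno_matrix
#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$G), "lines x", ncol(x$G), "markers\n")
  invisible(x)
}
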