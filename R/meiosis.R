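## Meiosis on ancestry mosaics.
##
## A haplotype is a per-chromosome list of 3-column matrices
## (start, end, founder) in 1-based inclusive bp coordinates that tile the
## chromosome.  A mosaic (one plant) holds two haplotypes.

new_haplotype <- function(founder, chrom_lengths) {
  h <- lapply(chrom_lengths, function(L) {
    matrix(c(1, L, founder), nrow = 1,
           dimnames = list(NULL, c("start", "end", "founder")))
  })
  names(h) <- names(chrom_lengths)
  h
}

new_mosaic <- function(hap1, hap2, line_id = NA_character_) {
  structure(list(line_id = line_id, haps = list(hap1, hap2)), class = "mosaic")
}

#' A fully inbred plant of a single founder
#'
#' @param founder founder index (1..K).
#' @param panel a \code{founder_panel}.
#' @export
founder_plant <- function(founder, panel) {
  h <- new_haplotype(founder, panel$chrom_lengths)
  new_mosaic(h, h, panel$founder_ids[founder])
}

## clip a tiling segment matrix to [s, e]
clip_segments <- function(m, s, e) {
  i1 <- findInterval(s, m[, 1])
  i2 <- findInterval(e, m[, 1])
  mm <- m[i1:i2, , drop = FALSE]
  mm[1, 1] <- s
  mm[nrow(mm), 2] <- e
  mm
}

## collapse consecutive rows with the same founder
merge_adjacent <- function(m) {
  if (nrow(m) < 2) return(m)
  keep <- c(TRUE, m[-1, 3] != m[-nrow(m), 3])
  if (all(keep)) return(m)
  idx <- cumsum(keep)
  out <- m[keep, , drop = FALSE]
  out[, 2] <- tapply(m[, 2], idx, max)
  out
}

## recombine two chromosome tilings at sorted breakpoints, starting from
## haplotype `first` (1 or 2); a breakpoint b splits between b and b+1
recombine_chr <- function(A, B, breaks, first) {
  L <- A[nrow(A), 2]
  if (length(breaks) == 0) return(if (first == 1) A else B)
  src <- list(A, B)
  bounds <- c(0, breaks, L)
  segs <- vector("list", length(bounds) - 1)
  cur <- first
  for (i in seq_len(length(bounds) - 1)) {
    segs[[i]] <- clip_segments(src[[cur]], bounds[i] + 1, bounds[i + 1])
    cur <- 3 - cur
  }
  merge_adjacent(do.call(rbind, segs))
}

#' Simulate one meiosis
#'
#' Crossover counts per chromosome are Poisson with mean equal to the
#' chromosome's genetic length in Morgans (Haldane model, no interference);
#' crossover positions are uniform on the genetic scale and mapped to bp by
#' a uniform cM/Mb map.  Zero-crossover meioses are allowed (no obligate
#' chiasma).
#'
#' @param plant a \code{mosaic}.
#' @param morgans named numeric vector, genetic length in Morgans per
#'   chromosome.
#' @return a haplotype (per-chromosome segment list).
#' @export
meiosis <- function(plant, morgans) {
  if (!inherits(plant, "mosaic")) stop("plant must be a mosaic")
  h1 <- plant$haps[[1]]; h2 <- plant$haps[[2]]
  out <- vector("list", length(h1))
  names(out) <- names(h1)
  for (c in seq_along(h1)) {
    A <- h1[[c]]; B <- h2[[c]]
    L <- A[nrow(A), 2]
    n_xo <- rpois(1, morgans[[c]])
    first <- sample.int(2, 1)
    if (n_xo == 0) {
      out[[c]] <- if (first == 1) A else B
      next
    }
    b <- floor(runif(n_xo) * (L - 1)) + 1
    tb <- table(b)
    b <- sort(as.numeric(names(tb)[tb %% 2 == 1]))  # coincident pairs cancel
    out[[c]] <- recombine_chr(A, B, b, first)
  }
  out
}

## founder ancestry of a haplotype chromosome at sorted positions
founder_at <- function(hap_chr, pos) {
  hap_chr[findInterval(pos, hap_chr[, 1]), 3]
}

## validate that a haplotype tiles every chromosome exactly
check_tiling <- function(hap, chrom_lengths) {
  for (c in seq_along(hap)) {
    m <- hap[[c]]
    if (m[1, 1] != 1 || m[nrow(m), 2] != chrom_lengths[[c]]) return(FALSE)
    if (nrow(m) > 1 && any(m[-1, 1] != m[-nrow(m), 2] + 1)) return(FALSE)
  }
  TRUE
}

#' Per-founder genome share of one plant
#'
#' Length-weighted fraction of the two haplotypes assigned to each founder.
#' @param plant a \code{mosaic}.
#' @param K number of founders.
#' @return numeric vector of length K summing to 1.
#' @export
founder_shares <- function(plant, K = 8) {
  tot <- numeric(K)
  for (h in plant$haps) for (m in h) {
    len <- m[, 2] - m[, 1] + 1
    tot <- tot + vapply(seq_len(K), function(k) sum(len[m[, 3] == k]), 0)
  }
  tot / sum(tot)
}

#' Fraction of the genome heterozygous by ancestry
#'
#' Length-weighted fraction of positions where the two haplotypes carry
#' different founder labels.
#' @param plant a \code{mosaic}.
#' @return fraction in [0, 1].
#' @export
het_fraction <- function(plant) {
  het <- tot <- 0
  for (c in seq_along(plant$haps[[1]])) {
    A <- plant$haps[[1]][[c]]; B <- plant$haps[[2]][[c]]
    L <- A[nrow(A), 2]
    cuts <- sort(unique(c(A[, 2], B[, 2])))
    starts <- c(1, head(cuts, -1) + 1)
    fa <- founder_at(A, starts); fb <- founder_at(B, starts)
    het <- het + sum((cuts - starts + 1)[fa != fb])
    tot <- tot + L
  }
  het / tot
}

#' Count ancestry junctions in one plant
#'
#' A junction is an internal segment boundary on either haplotype.
#' @param plant a \code{mosaic}.
#' @export
junction_count <- function(plant) {
  sum(vapply(plant$haps, function(h)
    sum(vapply(h, nrow, 0L) - 1L), 0))
}
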