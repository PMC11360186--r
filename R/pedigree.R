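## The eight-way funnel pedigree: three rounds of outcrossing
## (2-way, 4-way, 8-way F1) followed by selfing under single-seed descent.

#' Define the crossing design
#'
#' @param n_lines number of lines to simulate.
#' @param n_selfing_gens selfing generations after the eight-way F1
#'   (default 6, giving F6-equivalent lines).
#' @param funnel permutation of 1..8 giving the founder order in the
#'   funnel: 2-way crosses are (1,2), (3,4), (5,6), (7,8) of this order,
#'   then (12)x(34) and (56)x(78), then the eight-way cross.  The true
#'   pairings of a real population are rarely published, so the order is
#'   configurable; \code{"random"} draws an independent random funnel per
#'   line.
#' @param cm_per_mb uniform genetic map density (centimorgan per megabase).
#' @return a \code{crossing_design}.
#' @export
crossing_design <- function(n_lines, n_selfing_gens = 6, funnel = 1:8,
                            cm_per_mb = 4) {
  if (n_selfing_gens < 0) stop("n_selfing_gens must be >= 0")
  if (n_lines < 1) stop("n_lines must be >= 1")
  if (!identical(funnel, "random")) {
    funnel <- as.integer(funnel)
    if (length(funnel) != 8 || anyDuplicated(funnel) ||
        !all(sort(funnel) == 1:8))
      stop("funnel must use every founder exactly once")
  }
  structure(list(n_lines = n_lines, n_selfing_gens = n_selfing_gens,
                 funnel = funnel, cm_per_mb = cm_per_mb),
            class = "crossing_design")
}

## cross two plants; selection acts on the gametes of each sex
cross_plants <- function(mother, father, loci, panel, morgans) {
  egg <- make_gamete(mother, "female", loci, panel, morgans)
  pollen <- make_gamete(father, "male", loci, panel, morgans)
  new_mosaic(egg, pollen)
}

## advance one SSD generation; zygote-viability loci reject affected
## offspring (replaced by a resampled selfed sibling, so n is preserved)
self_advance <- function(plant, loci, viab, panel, morgans,
                         max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    off <- cross_plants(plant, plant, loci, panel, morgans)
    ok <- TRUE
    for (v in viab) {
      if (.viability_affected(off, v, panel) && runif(1) < v$s) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(off)
  }
  stop("no viable selfed offspring after ", max_tries, " attempts")
}

#' Simulate the full funnel pedigree
#'
#' Each line is built independently: the four two-way F1s of its funnel,
#' two four-way crosses, one eight-way cross, then
#' \code{design$n_selfing_gens} generations of selfing by single-seed
#' descent.  Gamete-killer loci act in every cross on the affected sex;
#' zygote-viability loci act during selfing.
#'
#' @param panel a \code{founder_panel}.
#' @param design a \code{crossing_design}.
#' @param selection_loci list of \code{selection_locus} objects.
#' @param seed optional RNG seed for the run.
#' @param keep_f1 if TRUE, attach each line's eight-way F1 as attribute
#'   \code{"f1"} (list parallel to the lines).
#' @return list of \code{mosaic} objects (one per line).
#' @export
run_pedigree <- function(panel, design, selection_loci = list(),
                         seed = NULL, keep_f1 = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  morgans <- panel$chrom_lengths / 1e6 * design$cm_per_mb / 100
  gam <- Filter(function(l) l$mode != "zygote_viability", selection_loci)
  viab <- Filter(function(l) l$mode == "zygote_viability", selection_loci)
  lines <- vector("list", design$n_lines)
  f1s <- if (keep_f1) vector("list", design$n_lines) else NULL
  for (i in seq_len(design$n_lines)) {
    ord <- if (identical(design$funnel, "random")) sample(8) else design$funnel
    two_way <- lapply(seq(1, 8, by = 2), function(j)
      new_mosaic(new_haplotype(ord[j], panel$chrom_lengths),
                 new_haplotype(ord[j + 1], panel$chrom_lengths)))
    four_way <- list(
      cross_plants(two_way[[1]], two_way[[2]], gam, panel, morgans),
      cross_plants(two_way[[3]], two_way[[4]], gam, panel, morgans))
    plant <- cross_plants(four_way[[1]], four_way[[2]], gam, panel, morgans)
    if (keep_f1) f1s[[i]] <- plant
    for (g in seq_len(design$n_selfing_gens))
      plant <- self_advance(plant, gam, viab, panel, morgans)
    plant$line_id <- sprintf("MG%04d", i)
    lines[[i]] <- plant
  }
  if (keep_f1) attr(lines, "f1") <- f1s
  lines
}

#' Ground-truth ancestry segments of simulated lines
#'
#' @param mosaics list of \code{mosaic} objects.
#' @return data.frame with columns line, hap, chrom, start, end, founder.
#' @export
mosaic_segments <- function(mosaics) {
  out <- vector("list", length(mosaics) * 2)
  j <- 0
  for (m in mosaics) for (h in 1:2) {
    segs <- do.call(rbind, lapply(names(m$haps[[h]]), function(c) {
      s <- m$haps[[h]][[c]]
      data.frame(line = m$line_id, hap = h, chrom = c,
                 start = s[, 1], end = s[, 2], founder = s[, 3])
    }))
    j <- j + 1
    out[[j]] <- segs
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
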