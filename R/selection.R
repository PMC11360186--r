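## Selection loci acting on gametes or zygotes during the pedigree.
##
## Gamete killers model hybrid-incompatibility systems: in a heterozygous
## plant, gametes of one sex that carry the sensitive (victim) allele are
## eliminated with probability s.  `carriers` names the founders whose
## allele is safe (the killer allele for a pollen killer, the protected
## allele for a killer-protector system); all other founders carry the
## victim allele.

#' Define a gamete-killer selection locus
#'
#' @param mode \code{"pollen_killer"} (acts on male gametes) or
#'   \code{"female_killer_protector"} (acts on female gametes).
#' @param chrom chromosome name.
#' @param pos position in bp.
#' @param carriers character vector of founder ids carrying the safe
#'   (killer/protected) allele; the remaining founders are victims.
#' @param s selection coefficient in [0, 1]: probability that a victim
#'   gamete from a heterozygous plant is eliminated.
#' @return a \code{selection_locus}.
#' @export
selection_locus <- function(mode = c("pollen_killer", "female_killer_protector"),
                            chrom, pos, carriers, s = 1) {
  mode <- match.arg(mode)
  if (s < 0 || s > 1) stop("s must be in [0, 1]")
  structure(list(mode = mode, chrom = chrom, pos = pos,
                 carriers = carriers, s = s),
            class = "selection_locus")
}

#' Define a multi-locus zygote-viability locus
#'
#' Models selection against a deleterious functional allele combination
#' (e.g. a photoperiod-gene combination causing unfilled grain): a plant is
#' affected if, at every component locus, at least one haplotype carries a
#' functional allele.  During single-seed descent an affected plant is
#' discarded with probability s and replaced by a resampled selfed sibling.
#'
#' @param chrom,pos parallel vectors of component-locus coordinates.
#' @param functional list (one element per component) of founder-id vectors
#'   carrying the functional allele.
#' @param s selection coefficient in [0, 1].
#' @return a \code{selection_locus} of mode \code{"zygote_viability"}.
#' @export
viability_locus <- function(chrom, pos, functional, s = 1) {
  if (length(chrom) != length(pos) || length(pos) != length(functional))
    stop("chrom, pos and functional must have equal length")
  if (s < 0 || s > 1) stop("s must be in [0, 1]")
  structure(list(mode = "zygote_viability", chrom = chrom, pos = pos,
                 functional = functional, s = s),
            class = "selection_locus")
}

## founder index sets resolved against a panel
.carrier_idx <- function(ids, panel) {
  idx <- match(ids, panel$founder_ids)
  if (anyNA(idx)) stop("unknown founder id in carrier set")
  idx
}

## is the plant heterozygous (safe/victim) at a gamete-killer locus?
.killer_het <- function(plant, locus, panel) {
  safe <- .carrier_idx(locus$carriers, panel)
  f1 <- founder_at(plant$haps[[1]][[locus$chrom]], locus$pos)
  f2 <- founder_at(plant$haps[[2]][[locus$chrom]], locus$pos)
  (f1 %in% safe) != (f2 %in% safe)
}

#' Filter gametes through gamete-killer loci
#'
#' In a plant heterozygous at a killer locus, gametes of the affected sex
#' carrying the victim allele are removed with probability s; homozygous
#' plants transmit Mendelianly (no filtering).
#'
#' @param gametes list of haplotypes produced from \code{plant}.
#' @param plant the parent \code{mosaic}.
#' @param loci list of \code{selection_locus} objects.
#' @param panel a \code{founder_panel}.
#' @param sex \code{"male"} or \code{"female"}: which gametes these are.
#' @return the surviving subset of \code{gametes}.
#' @export
apply_gamete_selection <- function(gametes, plant, loci, panel,
                                   sex = c("male", "female")) {
  sex <- match.arg(sex)
  want <- if (sex == "male") "pollen_killer" else "female_killer_protector"
  for (locus in loci) {
    if (inherits(locus, "selection_locus") && locus$mode == "zygote_viability") next
    if (locus$mode != want) next
    if (!locus$chrom %in% names(panel$chrom_lengths) ||
        locus$pos > panel$chrom_lengths[[locus$chrom]])
      stop("selection locus off the simulated genome")
    if (!.killer_het(plant, locus, panel)) next
    safe <- .carrier_idx(locus$carriers, panel)
    victim <- vapply(gametes, function(g)
      !(founder_at(g[[locus$chrom]], locus$pos) %in% safe), TRUE)
    killed <- victim & runif(length(gametes)) < locus$s
    gametes <- gametes[!killed]
  }
  gametes
}

## one surviving gamete by rejection sampling
make_gamete <- function(plant, sex, loci, panel, morgans, max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    g <- meiosis(plant, morgans)
    if (length(apply_gamete_selection(list(g), plant, loci, panel, sex)) == 1)
      return(g)
  }
  stop("no surviving gamete after ", max_tries, " meioses")
}

## does the plant carry the deleterious combination of a viability locus?
.viability_affected <- function(plant, locus, panel) {
  for (i in seq_along(locus$pos)) {
    fun <- .carrier_idx(locus$functional[[i]], panel)
    f1 <- founder_at(plant$haps[[1]][[locus$chrom[i]]], locus$pos[i])
    f2 <- founder_at(plant$haps[[2]][[locus$chrom[i]]], locus$pos[i])
    if (!(f1 %in% fun) && !(f2 %in% fun)) return(FALSE)
  }
  TRUE
}
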